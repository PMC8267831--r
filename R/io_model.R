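#' @useDynLib taxoresolve, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom rpois setNames quantile pnorm qnorm sd
#' @importFrom utils combn read.delim write.table head
#' @import methods
"_PACKAGE"

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

MARKER_VOCAB <- c("dmdA", "dmdB", "dmdC",
                  "dddW", "dddP", "dddQ", "dddD", "dddL", "dddY",
                  "luxI", "luxR", "16S", "none")

DDD_GENES <- c("dddW", "dddP", "dddQ", "dddD", "dddL", "dddY")

#' Construct a gene table for a strain record
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param nucleotide_seq CDS sequences (uppercase strings).
#' @param protein_seq translated sequences; `NA` for non-coding genes (16S).
#' @param marker_label controlled-vocabulary marker label. Anything starting
#'   with `"qcm"` is treated as a quality-control marker gene; the remaining
#'   labels must come from the phenotype marker vocabulary or be `"none"`.
#' @return a data.frame with one row per gene and a `codon_ok` column marking
#'   genes usable in codon-aware stages (CDS length equal to 3x protein
#'   length).
#' @export
gene_table <- function(gene_id, nucleotide_seq, protein_seq = NA_character_,
                       marker_label = "none") {
  stopifnot(!anyDuplicated(gene_id))
  df <- data.frame(gene_id = as.character(gene_id),
                   nucleotide_seq = toupper(as.character(nucleotide_seq)),
                   protein_seq = toupper(as.character(protein_seq)),
                   marker_label = as.character(marker_label),
                   stringsAsFactors = FALSE)
  bad_label <- !(df$marker_label %in% MARKER_VOCAB |
                   startsWith(df$marker_label, "qcm"))
  if (any(bad_label)) {
    stop("unknown marker_label(s): ",
         paste(unique(df$marker_label[bad_label]), collapse = ", "))
  }
  nt_len <- nchar(df$nucleotide_seq)
  aa_len <- ifelse(is.na(df$protein_seq), NA_integer_, nchar(df$protein_seq))
  df$codon_ok <- !is.na(aa_len) & nt_len == 3L * aa_len
  not_div3 <- !is.na(df$nucleotide_seq) & nt_len %% 3L != 0L &
    !is.na(df$protein_seq)
  if (any(not_div3)) {
    warning("CDS length not divisible by 3 for gene(s): ",
            paste(df$gene_id[not_div3], collapse = ", "),
            "; excluded from codon-aware stages")
    df$codon_ok[not_div3] <- FALSE
  }
  df
}

#' Construct a strain record
#'
#' One genome with its annotations and taxonomy metadata.
#'
#' @param strain_id unique strain token.
#' @param genome named character vector of contig sequences (uppercase).
#' @param genes gene table as built by [gene_table()].
#' @param genus,species claimed name tokens.
#' @param is_type_species is this strain the type species of its genus?
#' @param genus_year year of first valid description of the claimed genus.
#' @param environment one of marine/terrestrial/freshwater/other.
#' @param nacl_percent percent w/v NaCl of the isolation environment, or NA.
#' @param family claimed family label, or NA.
#' @param plasmid optional logical vector flagging plasmid contigs, which are
#'   excluded from genome-wide metrics.
#' @export
strain_record <- function(strain_id, genome, genes,
                          genus, species, is_type_species = FALSE,
                          genus_year = 1900L,
                          environment = "other", nacl_percent = NA_real_,
                          family = NA_character_, plasmid = NULL) {
  genome <- toupper(as.character(genome))
  if (is.null(names(genome))) {
    names(genome) <- paste0(strain_id, "_c", seq_along(genome))
  }
  letters_used <- unique(strsplit(paste(genome, collapse = ""), "")[[1]])
  if (!all(letters_used %in% IUPAC_NT)) {
    stop("genome of ", strain_id, " contains non-IUPAC characters: ",
         paste(setdiff(letters_used, IUPAC_NT), collapse = ","))
  }
  if (!is.na(genus_year) && genus_year < 1753L) {
    stop("genus_year must be >= 1753")
  }
  if (!is.na(nacl_percent) && (nacl_percent < 0 || nacl_percent > 40)) {
    stop("nacl_percent must lie in [0, 40]")
  }
  if (is.null(plasmid)) plasmid <- rep(FALSE, length(genome))
  structure(list(strain_id = as.character(strain_id), genome = genome,
                 genes = genes, genus = as.character(genus),
                 species = as.character(species),
                 is_type_species = isTRUE(is_type_species),
                 genus_year = as.integer(genus_year),
                 environment = as.character(environment),
                 nacl_percent = as.numeric(nacl_percent),
                 family = as.character(family), plasmid = plasmid),
            class = "strain_record")
}

#' @export
print.strain_record <- function(x, ...) {
  cat("<strain_record>", x$strain_id, "-", x$genus, x$species,
      sprintf("(%d contigs, %d genes)\n", length(x$genome), nrow(x$genes)))
  invisible(x)
}

#' Validate a list of strain records as a dataset
#'
#' @param records list of [strain_record()] objects.
#' @return the same list, named by strain_id.
#' @export
as_dataset <- function(records) {
  ids <- vapply(records, function(r) r$strain_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate strain_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(records) <- ids
  records
}

#' Decision thresholds and tunable parameters
#'
#' Defaults follow the published species boundaries (dDDH 70, ANI 95), the
#' genome-quality screen (completeness >= 95, contamination <= 5), the
#' bootstrap collapse rule (50), the high-salinity boundary (3.5 percent w/v
#' NaCl), and the ten-closest-relatives shortlist.
#'
#' @param ... named overrides of any default.
#' @export
default_thresholds <- function(...) {
  th <- list(
    dddh_species = 70, ani_species = 95, support_collapse = 50,
    completeness_min = 95, contamination_max = 5, nacl_high = 3.5,
    shortlist_k = 10L, alpha = 0.05,
    # core-genome clustering / alignment
    identity_threshold = 0.5,
    # ANI engine
    fragment_length = 1020L, ani_min_identity = 30, ani_min_coverage = 70,
    # AAI engine
    aai_min_identity = 30, aai_min_coverage = 70,
    # dDDH calibration: dDDH = 100 * exp(-dddh_rate * d); rate chosen so the
    # 95 percent ANI and 70 percent dDDH species boundaries coincide.
    dddh_rate = -log(0.7) / 0.05,
    # genus/family decision machinery
    ref_mode = "range", ref_quantile = c(0.025, 0.975),
    trait_diff_limit = 3L,
    family_support_min = 95, family_coverage_min = 0.9,
    max_between_pairs = 500L
  )
  dots <- list(...)
  th[names(dots)] <- dots
  th
}

# ---- Newick -----------------------------------------------------------------

#' Write a tree to Newick text
#'
#' Support values are written as internal-node labels (RAxML style), branch
#' lengths after colons.
#' @param tree an ape `phylo` object, optionally with `node.label` supports.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Read a Newick string into a tree
#'
#' @param text a Newick string.
#' @return an ape `phylo`; internal-node labels are kept as support values.
#' @export
read_newick <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    stop("unbalanced parentheses at position ", which(depth < 0)[1])
  }
  if (depth[length(depth)] != 0) {
    stop("unbalanced parentheses: ", depth[length(depth)],
         " unclosed at position ", length(depth))
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

# numeric view of node.label supports (NA when absent/empty)
node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

# ---- dataset directory IO ---------------------------------------------------

dataset_paths <- function(dir, id) {
  list(genome = file.path(dir, "genomes", paste0(id, "_genome.fna")),
       cds = file.path(dir, "genes", paste0(id, "_cds.fna")),
       protein = file.path(dir, "genes", paste0(id, "_protein.faa")),
       table = file.path(dir, "genes", paste0(id, "_genes.tsv")))
}

read_fasta_chr <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path)
  else Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

write_fasta_chr <- function(x, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(x)
  else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path)
}

#' Read a dataset directory into strain records
#'
#' Expects the layout written by [write_dataset()]: a `metadata.tsv` with at
#' least `strain_id`, `genus`, `species`, `is_type_species`, `genus_year`
#' columns, plus per-strain genome/CDS/protein FASTA files and gene tables.
#' Optional metadata columns (`environment`, `nacl_percent`, `family`) become
#' missing values when absent.
#'
#' @param dir dataset directory.
#' @return named list of [strain_record()] objects.
#' @export
read_dataset <- function(dir) {
  meta_file <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_file)) stop("metadata file not found: ", meta_file)
  meta <- read.delim(meta_file, stringsAsFactors = FALSE,
                     colClasses = "character")
  required <- c("strain_id", "genus", "species", "is_type_species",
                "genus_year")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$strain_id)) {
    stop("duplicate strain_id in metadata: ",
         paste(unique(meta$strain_id[duplicated(meta$strain_id)]),
               collapse = ", "))
  }
  opt <- function(col, default) {
    if (col %in% names(meta)) meta[[col]] else rep(default, nrow(meta))
  }
  env <- opt("environment", "other")
  nacl <- suppressWarnings(as.numeric(opt("nacl_percent", NA)))
  fam <- opt("family", NA_character_)
  records <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$strain_id[i]
    p <- dataset_paths(dir, id)
    if (!file.exists(p$genome)) {
      stop("genome file missing for strain ", id, ": ", p$genome)
    }
    genome <- read_fasta_chr(p$genome, "dna")
    gtab <- read.delim(p$table, stringsAsFactors = FALSE,
                       colClasses = "character")
    cds <- if (file.exists(p$cds)) read_fasta_chr(p$cds, "dna") else character()
    prot <- if (file.exists(p$protein)) read_fasta_chr(p$protein, "aa")
    else character()
    genes <- gene_table(
      gene_id = gtab$gene_id,
      nucleotide_seq = unname(cds[gtab$gene_id]),
      protein_seq = ifelse(gtab$gene_id %in% names(prot),
                           unname(prot[gtab$gene_id]), NA_character_),
      marker_label = gtab$marker_label)
    records[[i]] <- strain_record(
      strain_id = id, genome = genome, genes = genes,
      genus = meta$genus[i], species = meta$species[i],
      is_type_species = meta$is_type_species[i] %in% c("TRUE", "true", "1"),
      genus_year = as.integer(meta$genus_year[i]),
      environment = env[i], nacl_percent = nacl[i], family = fam[i])
  }
  as_dataset(records)
}

#' Write strain records (and optional truth annotations) to a directory
#'
#' @param records named list of strain records.
#' @param dir output directory (created if needed).
#' @param truth optional list with elements `tree` (phylo), `taxonomy`
#'   (data.frame) and `ledger` (data.frame), as produced by the synthetic
#'   generator.
#' @export
write_dataset <- function(records, dir, truth = NULL) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(records, function(r) {
    data.frame(strain_id = r$strain_id, genus = r$genus, species = r$species,
               is_type_species = r$is_type_species, genus_year = r$genus_year,
               environment = r$environment, nacl_percent = r$nacl_percent,
               family = r$family, stringsAsFactors = FALSE)
  }))
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (r in records) {
    p <- dataset_paths(dir, r$strain_id)
    write_fasta_chr(r$genome, p$genome, "dna")
    write_fasta_chr(setNames(r$genes$nucleotide_seq, r$genes$gene_id),
                    p$cds, "dna")
    has_prot <- !is.na(r$genes$protein_seq)
    write_fasta_chr(setNames(r$genes$protein_seq[has_prot],
                             r$genes$gene_id[has_prot]), p$protein, "aa")
    write.table(r$genes[, c("gene_id", "marker_label")], p$table,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    if (!is.null(truth$tree)) {
      writeLines(write_newick(truth$tree), file.path(dir, "truth_tree.nwk"))
    }
    if (!is.null(truth$taxonomy)) {
      write.table(truth$taxonomy, file.path(dir, "truth_taxonomy.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(truth$ledger) && nrow(truth$ledger)) {
      write.table(truth$ledger, file.path(dir, "truth_ledger.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read/write a pipeline configuration
#'
#' Configuration is stored as JSON (one flat object of threshold overrides
#' plus an integer `seed`).
#' @param path file path.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- do.call(default_thresholds, cfg[setdiff(names(cfg), "seed")])
  th$seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 42L
  th
}

#' @rdname read_config
#' @param config named list of threshold overrides.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
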