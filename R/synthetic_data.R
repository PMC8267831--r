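# Synthetic dataset generator: a genus/species-labelled pure-birth phylogeny,
# genomes of clustered single-copy genes diverging along it under a
# Jukes-Cantor-style substitution process, injected label errors producing
# para-/polyphyly and over-split species, and family-conditional Bernoulli
# traits with their marker genes.

BASES <- c("A", "C", "G", "T")
BASE_CODES <- vapply(BASES, utf8ToInt, integer(1))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Default family-conditional trait probabilities
#'
#' The two families of the generator mirror the published contrast between a
#' marine-dominated lineage (famA) and the remainder of the family (famB):
#' high-salinity isolation 89 vs 39 percent, DMSP cleavage 64 vs 37,
#' DMSP demethylation 52 vs 7, AHL quorum sensing 56 vs 4.
#' @export
default_trait_probs <- function() {
  data.frame(family = c("famA", "famB"),
             high_salinity = c(0.89, 0.39),
             dmsp_cleavage = c(0.64, 0.37),
             dmsp_demethylation = c(0.52, 0.07),
             ahl_qs = c(0.56, 0.04),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The defaults are the generator's stated world: 120 tips, 60 genes of 250
#' codons, a pure-birth tree rescaled to unit root-to-tip depth, genus groups
#' cut at crown age 0.3, terminal branches uniformly extended by 0.24 (so
#' that distinct species always exceed species-level divergence while the
#' tree stays ultrametric), and an overall rate of 0.15 substitutions/site
#' per unit depth with codon positions at relative rates 0.4/0.3/2.3.
#'
#' @param n_tips number of strains (>= 4).
#' @param birth_rate pure-birth (Yule) speciation rate.
#' @param genus_depth crown-age cutoff defining genus groups (tree is unit
#'   depth).
#' @param n_genes number of protein-coding genes in the root genome.
#' @param gene_length_codons codons per gene.
#' @param site_mutation_rate substitutions/site across unit tree depth.
#' @param cp_rate_mult relative substitution rates of codon positions 1-3
#'   (normalized to mean 1).  The elevated third position keeps protein
#'   identity high while nucleotide divergence accumulates, as purifying
#'   selection does in real coding genomes.
#' @param accessory_gene_prob probability an accessory gene is absent from a
#'   genome.  A fixed `core_fraction` of genes is never dropped, so a core
#'   genome survives realistic accessory loss.
#' @param core_fraction fraction of genes never dropped.
#' @param trait_probs per-family Bernoulli probabilities, see
#'   [default_trait_probs()].
#' @param injections either NULL, a list of event lists (kind/target/detail)
#'   or a count list, e.g. `list(n_para = 2, n_poly = 2, n_split = 1)`.
#' @param seed integer seed; every stochastic stage derives its own seed from
#'   it.
#' @param species_floor uniform terminal-branch extension (tree units),
#'   setting the minimum divergence between distinct species.
#' @param s16_rate_factor rate multiplier for the conserved 16S-like gene.
#' @param s16_length length (nt) of the 16S-like gene.
#' @param n_qc_markers number of core genes labelled as single-copy QC
#'   markers.
#' @param split_divergence substitutions/site separating the two genomes of
#'   an injected species split.
#' @param n_basal number of basal monospecific tips grafted near the root and
#'   excluded from family membership.
#' @export
simulation_config <- function(n_tips = 120L, birth_rate = 1,
                              genus_depth = 0.3, n_genes = 60L,
                              gene_length_codons = 250L,
                              site_mutation_rate = 0.15,
                              cp_rate_mult = c(0.4, 0.3, 2.3),
                              accessory_gene_prob = 0.1,
                              core_fraction = 2 / 3,
                              trait_probs = default_trait_probs(),
                              injections = NULL, seed = 42L,
                              species_floor = 0.24, s16_rate_factor = 0.1,
                              s16_length = 1500L, n_qc_markers = 20L,
                              split_divergence = 0.003, n_basal = 0L) {
  stopifnot(n_tips >= 4, birth_rate > 0, genus_depth > 0, n_genes >= 1,
            gene_length_codons >= 10, site_mutation_rate >= 0,
            accessory_gene_prob >= 0, accessory_gene_prob <= 1,
            core_fraction > 0, core_fraction <= 1)
  if (!all(c("family", "high_salinity", "dmsp_cleavage", "dmsp_demethylation",
             "ahl_qs") %in% names(trait_probs))) {
    stop("trait_probs must have columns family, high_salinity, ",
         "dmsp_cleavage, dmsp_demethylation, ahl_qs")
  }
  pcols <- setdiff(names(trait_probs), "family")
  if (any(unlist(trait_probs[pcols]) < 0 | unlist(trait_probs[pcols]) > 1)) {
    stop("trait probabilities must lie in [0, 1]")
  }
  as.list(environment())
}

sense_codons <- function() {
  all <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  setdiff(all, STOP_CODONS)
}

random_cds <- function(n_codons) {
  cs <- sense_codons()
  paste0("ATG", paste(sample(cs, n_codons - 1L, replace = TRUE),
                      collapse = ""))
}

is_stop_codon <- function(c1, c2, c3) {
  T_ <- BASE_CODES[["T"]]; A_ <- BASE_CODES[["A"]]; G_ <- BASE_CODES[["G"]]
  (c1 == T_ & c2 == A_ & (c3 == A_ | c3 == G_)) |
    (c1 == T_ & c2 == G_ & c3 == A_)
}

# Jukes-Cantor-style mutation of an integer-coded sequence: substitution
# events arrive as Poisson(d) per site, each replacing the base by one of the
# three alternatives uniformly.  For coding sequences, codons that would
# become stops are repaired by redrawing the offending event's target base.
mutate_seq_int <- function(x, d, coding = FALSE, pos_w = NULL) {
  L <- length(x)
  n_ev <- rpois(1L, d * L)
  if (n_ev == 0L) return(x)
  if (is.null(pos_w) || !coding) {
    sites <- sample.int(L, n_ev, replace = TRUE)
  } else {
    w <- rep_len(pos_w / mean(pos_w), L)
    sites <- sample.int(L, n_ev, replace = TRUE, prob = w)
  }
  alt <- matrix(0L, 4, 3, dimnames = list(BASES, NULL))
  for (b in BASES) alt[b, ] <- BASE_CODES[setdiff(BASES, b)]
  pick <- sample.int(3L, n_ev, replace = TRUE)
  newb <- alt[cbind(match(x[sites], BASE_CODES), pick)]
  x[sites] <- newb
  if (!coding) return(x)
  for (iter in 1:10) {
    s <- seq.int(1L, L, 3L)
    stop_at <- which(is_stop_codon(x[s], x[s + 1L], x[s + 2L]))
    if (!length(stop_at)) break
    for (ci in stop_at) {
      pos <- s[ci] + 0:2
      hit <- intersect(pos, sites)
      p <- if (length(hit)) hit[sample.int(length(hit), 1L)]
      else pos[sample.int(3L, 1L)]
      cands <- setdiff(BASE_CODES, x[p])
      ok <- vapply(cands, function(b) {
        y <- x[pos]; y[p - s[ci] + 1L] <- b
        !is_stop_codon(y[1], y[2], y[3])
      }, logical(1))
      cands <- cands[ok]
      if (length(cands)) x[p] <- cands[sample.int(length(cands), 1L)]
    }
  }
  x
}

#' Simulate a genus/species-labelled taxonomy tree
#'
#' A pure-birth tree with `n_tips` tips, rescaled to unit root-to-tip depth.
#' The two children of the root define families famA and famB; genera are the
#' maximal clades whose crown age is at most `genus_depth`; species are tips.
#' Terminal branches are floored at `species_floor` so that every pair of
#' distinct species exceeds species-level divergence.
#'
#' @param config a [simulation_config()].
#' @return list with `tree` (phylo) and `taxonomy` (truth table: strain_id,
#'   family, genus, species, is_type_species, genus_year).
#' @export
simulate_taxonomy_tree <- function(config) {
  set.seed(config$seed)
  n <- config$n_tips
  tree <- ape::rphylo(n, birth = config$birth_rate, death = 0)
  tree$tip.label <- sprintf("t%03d", seq_len(n))
  d <- node_depths(tree)
  tree$edge.length <- tree$edge.length / max(d[seq_len(n)])
  h <- node_heights(tree)
  root <- tree_root(tree)
  kids <- tree_children(tree)
  tipsets <- tree_tipsets(tree)
  fam_kids <- kids[[root]]
  family <- setNames(rep(NA_character_, n), tree$tip.label)
  family[tipsets[[fam_kids[1]]]] <- "famA"
  family[tipsets[[fam_kids[2]]]] <- "famB"
  # genera: maximal clades with crown height <= genus_depth
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  eligible <- h <= config$genus_depth + 1e-12
  maximal <- which(eligible & !eligible[pmax(parent, 1L)] & parent > 0L)
  genera_tips <- lapply(maximal, function(nd) tipsets[[nd]])
  if (length(genera_tips) < 2L) {
    stop("genus_depth produced a single genus; use a smaller cutoff")
  }
  ord <- order(vapply(genera_tips, function(tp) min(match(tp, tree$tip.label)),
                      integer(1)))
  genera_tips <- genera_tips[ord]
  genus <- setNames(rep(NA_character_, n), tree$tip.label)
  for (gi in seq_along(genera_tips)) {
    genus[genera_tips[[gi]]] <- sprintf("g%02d", gi)
  }
  years <- sample(seq(1850L, 2015L), length(genera_tips))
  genus_year <- setNames(years[match(genus, sprintf("g%02d",
                                                    seq_along(genera_tips)))],
                         tree$tip.label)
  is_type <- setNames(rep(FALSE, n), tree$tip.label)
  for (gi in seq_along(genera_tips)) {
    tp <- genera_tips[[gi]]
    is_type[tp[which.min(match(tp, tree$tip.label))]] <- TRUE
  }
  # basal monospecific grafts: children of the root itself, below the split
  # of the two major lineages (so neither family clade contains them)
  if (config$n_basal > 0L) {
    for (b in seq_len(config$n_basal)) {
      lab <- sprintf("b%02d", b)
      tree <- ape::bind.tree(tree, single_tip_phylo(lab, 1),
                             where = tree_root(tree))
      family[lab] <- NA_character_
      genus[lab] <- paste0("bg", b)
      genus_year[lab] <- 2016L + b
      is_type[lab] <- TRUE
    }
  }
  # extend every terminal branch by the species floor: species are distinct
  # entities with a minimum divergence, and the uniform extension keeps the
  # tree ultrametric (so midpoint rooting recovers the true root)
  term <- tree$edge[, 2] <= length(tree$tip.label)
  tree$edge.length[term] <- tree$edge.length[term] + config$species_floor
  labs <- tree$tip.label
  taxonomy <- data.frame(strain_id = labs, family = family[labs],
                         genus = genus[labs],
                         species = sprintf("s%03d", seq_along(labs)),
                         is_type_species = is_type[labs],
                         genus_year = as.integer(genus_year[labs]),
                         stringsAsFactors = FALSE)
  list(tree = tree, taxonomy = taxonomy)
}

# gene complement of the root genome
root_gene_plan <- function(config) {
  n_core <- max(1L, ceiling(config$core_fraction * config$n_genes))
  data.frame(
    gene = c(sprintf("g%03d", seq_len(config$n_genes)), "s16"),
    core = c(seq_len(config$n_genes) <= n_core, TRUE),
    coding = c(rep(TRUE, config$n_genes), FALSE),
    marker = c(ifelse(seq_len(config$n_genes) <= min(config$n_qc_markers,
                                                     n_core),
                      sprintf("qcm%02d", seq_len(config$n_genes)), "none"),
               "16S"),
    stringsAsFactors = FALSE)
}

#' Evolve genomes along a taxonomy tree
#'
#' A root genome of random CDSs (plus one conserved 16S-like gene) evolves
#' tip-ward under per-site uniform substitution at `site_mutation_rate`
#' substitutions/site per unit branch length; accessory genes are dropped per
#' genome with `accessory_gene_prob`.
#'
#' @param tree phylo with branch lengths.
#' @param config a [simulation_config()].
#' @param taxonomy truth table from [simulate_taxonomy_tree()].
#' @param seed integer seed.
#' @return named list of [strain_record()] objects.
#' @export
evolve_genomes <- function(tree, config, taxonomy, seed = config$seed + 1L) {
  stopifnot(!is.null(tree$edge.length))
  set.seed(seed)
  plan <- root_gene_plan(config)
  root_genes <- lapply(seq_len(nrow(plan)), function(i) {
    if (plan$coding[i]) seq_to_int(random_cds(config$gene_length_codons))
    else seq_to_int(paste(sample(BASES, config$s16_length, replace = TRUE),
                          collapse = ""))
  })
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  genomes <- vector("list", n_all)
  genomes[[tree_root(tree)]] <- root_genes
  po <- ape::reorder.phylo(tree, "postorder")
  rate <- config$site_mutation_rate
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]; bl <- po$edge.length[e]
    genomes[[ch]] <- lapply(seq_len(nrow(plan)), function(i) {
      r <- if (plan$coding[i]) rate * bl else rate * bl *
        config$s16_rate_factor
      mutate_seq_int(genomes[[p]][[i]], r, coding = plan$coding[i],
                     pos_w = config$cp_rate_mult)
    })
  }
  records <- vector("list", n_tip)
  for (ti in seq_len(n_tip)) {
    id <- tree$tip.label[ti]
    keep <- plan$core | rbinom(nrow(plan), 1L, 1 - config$accessory_gene_prob)
    keep <- as.logical(keep)
    gidx <- which(keep)
    nts <- vapply(genomes[[ti]][gidx], int_to_seq, character(1))
    gene_ids <- paste0(id, "_", plan$gene[gidx])
    coding <- plan$coding[gidx]
    prots <- rep(NA_character_, length(gidx))
    if (any(coding)) {
      prots[coding] <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(nts[coding])))
    }
    genes <- gene_table(gene_ids, nts, prots, plan$marker[gidx])
    tx <- taxonomy[taxonomy$strain_id == id, ]
    records[[ti]] <- strain_record(
      strain_id = id, genome = setNames(paste(nts, collapse = ""), id),
      genes = genes, genus = tx$genus, species = tx$species,
      is_type_species = tx$is_type_species, genus_year = tx$genus_year,
      environment = "other", nacl_percent = NA_real_, family = tx$family)
  }
  as_dataset(records)
}

#' Draw family-conditional traits and insert their marker genes
#'
#' Per strain, Bernoulli draws for high-salinity isolation, DMSP cleavage,
#' DMSP demethylation and AHL quorum sensing with family-conditional
#' probabilities.  Positive draws insert the corresponding marker genes (all
#' of dmdA/B/C for demethylation, a random nonempty subset of the six ddd
#' lyases for cleavage, luxI+luxR for QS); `nacl_percent` is sampled above or
#' below 3.5 according to the high-salinity draw.
#'
#' @param records named list of strain records (with `family` set).
#' @param trait_probs per-family probability table.
#' @param seed integer seed.
#' @param marker_codons length of inserted marker CDSs, in codons.
#' @return list with updated `records` and the truth `traits` table.
#' @export
draw_traits <- function(records, trait_probs = default_trait_probs(),
                        seed = 43L, marker_codons = 100L) {
  set.seed(seed)
  fams <- unique(stats::na.omit(vapply(records, function(r) r$family,
                                       character(1))))
  missing_fam <- setdiff(fams, trait_probs$family)
  if (length(missing_fam)) {
    stop("trait probability table missing family row(s): ",
         paste(missing_fam, collapse = ", "))
  }
  traits <- data.frame(strain_id = character(), family = character(),
                       high_salinity = logical(), dmsp_cleavage = logical(),
                       dmsp_demethylation = logical(), ahl_qs = logical(),
                       stringsAsFactors = FALSE)
  for (id in names(records)) {
    r <- records[[id]]
    if (is.na(r$family)) {
      draws <- c(high_salinity = FALSE, dmsp_cleavage = FALSE,
                 dmsp_demethylation = FALSE, ahl_qs = FALSE)
    } else {
      pr <- trait_probs[trait_probs$family == r$family, ]
      draws <- c(high_salinity = runif(1) < pr$high_salinity,
                 dmsp_cleavage = runif(1) < pr$dmsp_cleavage,
                 dmsp_demethylation = runif(1) < pr$dmsp_demethylation,
                 ahl_qs = runif(1) < pr$ahl_qs)
    }
    new_markers <- character()
    if (draws[["dmsp_demethylation"]]) {
      new_markers <- c(new_markers, "dmdA", "dmdB", "dmdC")
    }
    if (draws[["dmsp_cleavage"]]) {
      k <- sample.int(length(DDD_GENES), 1L)
      new_markers <- c(new_markers, sample(DDD_GENES, k))
    }
    if (draws[["ahl_qs"]]) new_markers <- c(new_markers, "luxI", "luxR")
    if (length(new_markers)) {
      nts <- vapply(seq_along(new_markers),
                    function(i) random_cds(marker_codons), character(1))
      prots <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(nts)))
      add <- gene_table(paste0(id, "_", new_markers), nts, prots, new_markers)
      r$genes <- rbind(r$genes, add)
      r$genome <- setNames(paste0(r$genome[1], paste(nts, collapse = "")), id)
    }
    if (!is.na(r$family)) {
      if (draws[["high_salinity"]]) {
        r$nacl_percent <- runif(1, 3.5, 12)
        r$environment <- if (runif(1) < 0.9) "marine" else "other"
      } else {
        r$nacl_percent <- runif(1, 0.1, 3.39)
        r$environment <- sample(c("terrestrial", "freshwater", "other"), 1L,
                                prob = c(0.4, 0.3, 0.3))
      }
    }
    records[[id]] <- r
    traits <- rbind(traits, data.frame(strain_id = id, family = r$family,
                                       t(draws), stringsAsFactors = FALSE))
  }
  list(records = records, traits = traits)
}

# re-derive the genes/genome of a record after mutating every gene by d
mutate_record <- function(r, d, s16_factor = 0.1, new_id = r$strain_id,
                          pos_w = NULL) {
  genes <- r$genes
  for (i in seq_len(nrow(genes))) {
    rate <- if (genes$marker_label[i] == "16S") d * s16_factor else d
    x <- mutate_seq_int(seq_to_int(genes$nucleotide_seq[i]), rate,
                        coding = genes$codon_ok[i], pos_w = pos_w)
    genes$nucleotide_seq[i] <- int_to_seq(x)
    if (!is.na(genes$protein_seq[i]) && genes$codon_ok[i]) {
      genes$protein_seq[i] <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(genes$nucleotide_seq[i])))
    }
  }
  genes$gene_id <- sub(paste0("^", r$strain_id, "_"), paste0(new_id, "_"),
                       genes$gene_id)
  r$genes <- genes
  r$strain_id <- new_id
  r$genome <- setNames(paste(genes$nucleotide_seq, collapse = ""), new_id)
  r
}

#' Sample feasible misclassification-injection events
#'
#' Chooses event targets so that each injected event is detectable in
#' principle and no two events collide on the same taxon: a paraphyly event
#' relabels a crown tip of one genus into its exact sister genus; a polyphyly
#' event relabels an entire well-separated genus clade with another genus'
#' name; a species split duplicates one tip into a barely diverged pair with
#' distinct species names.
#'
#' @param tree truth tree.
#' @param taxonomy truth taxonomy table.
#' @param n_para,n_poly,n_split requested event counts.
#' @param seed integer seed.
#' @return list of event descriptors for [inject_misclassifications()].
#' @export
sample_injection_events <- function(tree, taxonomy, n_para = 0L, n_poly = 0L,
                                    n_split = 0L, seed = 44L) {
  set.seed(seed)
  tipsets <- tree_tipsets(tree)
  kids <- tree_children(tree)
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  genera <- split(taxonomy$strain_id, taxonomy$genus)
  genus_of <- setNames(taxonomy$genus, taxonomy$strain_id)
  type_of <- setNames(taxonomy$is_type_species, taxonomy$strain_id)
  crown <- vapply(genera, function(tp) mrca_node(tree, tp), integer(1))
  pd <- ape::cophenetic.phylo(tree)
  multi <- names(genera)[lengths(genera) >= 2L]
  within_max <- vapply(multi, function(g) {
    tp <- genera[[g]]; max(pd[tp, tp])
  }, numeric(1))
  max_within <- max(within_max)
  used <- character()
  events <- list()
  # polyphyly first: it removes two genera each from the monophyletic
  # reference, which the paraphyly detectability filter must know about
  poly_done <- 0L
  cand_z <- names(genera)[vapply(names(genera), function(g) {
    tp <- genera[[g]]
    min(pd[tp, setdiff(colnames(pd), tp)]) >= 1.15 * max_within
  }, logical(1))]
  if (length(cand_z)) cand_z <- sample(cand_z)
  for (z in cand_z) {
    if (poly_done >= n_poly) break
    if (z %in% used) next
    xs <- setdiff(multi, c(used, z))
    xs <- xs[vapply(xs, function(x) {
      # the relabelled group must come out polyphyletic, not paraphyletic:
      # its intruders must not themselves form a clade
      comb <- c(genera[[x]], genera[[z]])
      intr <- setdiff(tipsets[[mrca_node(tree, comb)]], comb)
      length(intr) > 0 &&
        any(tipsets[[mrca_node(tree, intr)]] %in% comb)
    }, logical(1))]
    if (!length(xs)) next
    x <- sample(xs, 1L)
    used <- c(used, x, z)
    events[[length(events) + 1L]] <-
      list(kind = "polyphyly", target = x, detail = list(clade_genus = z))
    poly_done <- poly_done + 1L
  }
  if (poly_done < n_poly) {
    warning("only ", poly_done, " feasible polyphyly events found")
  }
  # paraphyly
  para_done <- 0L
  for (g in sample(multi)) {
    if (para_done >= n_para) break
    if (g %in% used) next
    cr <- crown[[g]]
    p <- parent[cr]
    if (p == 0L) next
    sib <- setdiff(kids[[p]], cr)
    if (length(sib) != 1L) next
    sib_tips <- tipsets[[sib]]
    sib_gen <- unique(genus_of[sib_tips])
    if (length(sib_gen) != 1L || sib_gen == g || sib_gen %in% used) next
    if (!setequal(sib_tips, genera[[sib_gen]])) next
    tip_kids <- kids[[cr]][kids[[cr]] <= n_tip]
    tip_kids <- tree$tip.label[tip_kids]
    tip_kids <- tip_kids[!type_of[tip_kids]]
    # detectability: the relabelled tip must not be farther from its true
    # genus than the within-genus pairs of the genera that stay in the
    # monophyletic reference, or the "within expected range" rule cannot
    # support the transfer back
    mw_ref <- suppressWarnings(
      max(within_max[setdiff(multi, c(used, g, sib_gen))]))
    if (!is.finite(mw_ref)) next
    tip_kids <- tip_kids[vapply(tip_kids, function(x) {
      max(pd[x, setdiff(genera[[g]], x)]) <= 0.95 * mw_ref
    }, logical(1))]
    if (!length(tip_kids)) next
    used <- c(used, g, sib_gen)
    events[[length(events) + 1L]] <-
      list(kind = "paraphyly", target = sib_gen,
           detail = list(tip = sample(tip_kids, 1L), from_genus = g))
    para_done <- para_done + 1L
  }
  if (para_done < n_para) {
    warning("only ", para_done, " feasible paraphyly events found")
  }
  # species splits
  free_tips <- taxonomy$strain_id[!(taxonomy$genus %in% used)]
  split_done <- 0L
  if (length(free_tips)) free_tips <- sample(free_tips)
  for (t in free_tips) {
    if (split_done >= n_split) break
    if (genus_of[[t]] %in% used) next
    used <- c(used, genus_of[[t]])
    events[[length(events) + 1L]] <-
      list(kind = "species_split", target = t,
           detail = list(new_tip = paste0(t, "b")))
    split_done <- split_done + 1L
  }
  if (split_done < n_split) {
    warning("only ", split_done, " feasible species_split events found")
  }
  events
}

#' Inject misclassifications into a labelled dataset
#'
#' Applies label errors to the claimed taxonomy (the truth tree and truth
#' taxonomy are untouched) and returns a truth ledger stating the expected
#' resolution of each event.
#'
#' @param records named list of strain records (claimed labels).
#' @param tree the truth tree (modified only by species splits, which add a
#'   barely diverged sister tip).
#' @param events list of event descriptors, see [sample_injection_events()].
#' @param traits optional trait truth table to extend for split tips.
#' @param split_divergence substitutions/site for the injected split pair.
#' @param seed integer seed (genome mutation of split tips).
#' @param cp_rate_mult codon-position rate multipliers for the split-pair
#'   mutation.
#' @return list with `records`, `tree`, `ledger` and `traits`.
#' @export
inject_misclassifications <- function(records, tree, events, traits = NULL,
                                      split_divergence = 0.003, seed = 45L,
                                      cp_rate_mult = NULL) {
  set.seed(seed)
  touched <- character()
  ledger <- data.frame(event_id = integer(), kind = character(),
                       target = character(), tips = character(),
                       expected_action = character(),
                       expected_subjects = character(),
                       expected_destination = character(),
                       stringsAsFactors = FALSE)
  genus_of <- vapply(records, function(r) r$genus, character(1))
  for (k in seq_along(events)) {
    ev <- events[[k]]
    involved <- switch(ev$kind,
      paraphyly = c(ev$target, ev$detail$from_genus),
      polyphyly = c(ev$target, ev$detail$clade_genus),
      species_split = genus_of[[ev$target]],
      genus_outlier = ev$target,
      stop("unknown injection kind: ", ev$kind))
    if (any(involved %in% touched)) {
      stop("injection event ", k, " collides with a previous event on ",
           paste(intersect(involved, touched), collapse = ", "))
    }
    touched <- c(touched, involved)
    if (ev$kind == "paraphyly") {
      x <- ev$detail$tip
      records[[x]]$genus <- ev$target
      records[[x]]$is_type_species <- FALSE
      records[[x]]$genus_year <-
        records[[which(genus_of == ev$target)[1]]]$genus_year
      ledger <- rbind(ledger, data.frame(
        event_id = k, kind = "paraphyly", target = ev$target, tips = x,
        expected_action = "transfer_species", expected_subjects = x,
        expected_destination = ev$detail$from_genus,
        stringsAsFactors = FALSE))
    } else if (ev$kind == "polyphyly") {
      z_tips <- names(records)[genus_of == ev$detail$clade_genus]
      yr <- records[[which(genus_of == ev$target)[1]]]$genus_year
      for (t in z_tips) {
        records[[t]]$genus <- ev$target
        records[[t]]$is_type_species <- FALSE
        records[[t]]$genus_year <- yr
      }
      ledger <- rbind(ledger, data.frame(
        event_id = k, kind = "polyphyly", target = ev$target,
        tips = paste(sort(z_tips), collapse = ";"),
        expected_action = "new_genus",
        expected_subjects = paste(sort(z_tips), collapse = ";"),
        expected_destination = NA_character_, stringsAsFactors = FALSE))
    } else if (ev$kind == "species_split") {
      t <- ev$target
      tb <- ev$detail$new_tip
      rb <- mutate_record(records[[t]], split_divergence, new_id = tb,
                          pos_w = cp_rate_mult)
      rb$species <- paste0(records[[t]]$species, "b")
      rb$is_type_species <- FALSE
      records[[tb]] <- rb
      tree <- ape::bind.tree(tree, single_tip_phylo(tb, 0.005),
                             where = which(tree$tip.label == t),
                             position = 0.005)
      if (!is.null(traits)) {
        tr <- traits[traits$strain_id == t, ]
        tr$strain_id <- tb
        traits <- rbind(traits, tr)
      }
      ledger <- rbind(ledger, data.frame(
        event_id = k, kind = "species_split", target = t,
        tips = paste(t, tb, sep = ";"),
        expected_action = "merge_species",
        expected_subjects = paste(sort(c(t, tb)), collapse = ";"),
        expected_destination = records[[t]]$species,
        stringsAsFactors = FALSE))
    } else if (ev$kind == "genus_outlier") {
      # graft a deep-branching tip into a genus label
      t <- ev$detail$tip
      records[[t]]$genus <- ev$target
      records[[t]]$is_type_species <- FALSE
      ledger <- rbind(ledger, data.frame(
        event_id = k, kind = "genus_outlier", target = ev$target, tips = t,
        expected_action = "new_genus", expected_subjects = t,
        expected_destination = NA_character_, stringsAsFactors = FALSE))
    }
  }
  list(records = as_dataset(records), tree = tree, ledger = ledger,
       traits = traits)
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_taxonomy_tree()], [evolve_genomes()], [draw_traits()] and,
#' if requested, [inject_misclassifications()] with seeds derived from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `records`, `tree` (the truth tree, including any
#'   injected split cherries) and `truth` (tree, taxonomy, ledger, traits).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  tax <- simulate_taxonomy_tree(config)
  records <- evolve_genomes(tax$tree, config, tax$taxonomy,
                            seed = config$seed + 1L)
  tr <- draw_traits(records, config$trait_probs, seed = config$seed + 2L)
  records <- tr$records
  traits <- tr$traits
  tree <- tax$tree
  ledger <- NULL
  taxonomy <- tax$taxonomy
  if (!is.null(config$injections)) {
    events <- config$injections
    if (!is.null(events$n_para) || !is.null(events$n_poly) ||
        !is.null(events$n_split)) {
      events <- sample_injection_events(
        tree, taxonomy,
        n_para = events$n_para %||% 0L, n_poly = events$n_poly %||% 0L,
        n_split = events$n_split %||% 0L, seed = config$seed + 3L)
    }
    inj <- inject_misclassifications(records, tree, events, traits = traits,
                                     split_divergence =
                                       config$split_divergence,
                                     seed = config$seed + 4L,
                                     cp_rate_mult = config$cp_rate_mult)
    records <- inj$records
    tree <- inj$tree
    ledger <- inj$ledger
    traits <- inj$traits
    for (t in setdiff(names(records), taxonomy$strain_id)) {
      src <- sub("b$", "", t)
      row <- taxonomy[taxonomy$strain_id == src, ]
      row$strain_id <- t
      row$is_type_species <- FALSE
      taxonomy <- rbind(taxonomy, row)
    }
  }
  if (is.null(ledger)) {
    ledger <- data.frame(event_id = integer(), kind = character(),
                         target = character(), tips = character(),
                         expected_action = character(),
                         expected_subjects = character(),
                         expected_destination = character(),
                         stringsAsFactors = FALSE)
  }
  list(records = records, tree = tree,
       truth = list(tree = tree, taxonomy = taxonomy, ledger = ledger,
                    traits = traits),
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
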