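# End-to-end orchestration: QC -> core genome -> tree -> metrics -> phyly ->
# decision rules -> proposals, plus the shortlist-based placement workflow
# for new genomes.

#' Assemble the analysis context for the decision engine
#'
#' Runs the QC screen, builds the core-genome alignment, infers the
#' bootstrapped NJ tree, roots it (outgroup or midpoint), collapses
#' low-support nodes, computes the cheap all-pairs metrics (patristic
#' distances on the full rooted tree; codon-position similarities) and
#' classifies every claimed genus on the collapsed tree.
#'
#' @param records named list of strain records.
#' @param thresholds a [default_thresholds()] list.
#' @param n_boot bootstrap replicates for the core-genome tree.
#' @param seed integer seed (bootstrap resampling and subsampling).
#' @param outgroup optional outgroup strain ids (pruned after rooting).
#' @param tree optional externally inferred rooted tree with supports,
#'   bypassing in-package inference.
#' @param traits optional trait profile table ([trait_profiles()] format);
#'   computed from marker labels when NULL.
#' @param run_qc run the marker-based QC screen first?
#' @return an `analysis_context` list.
#' @export
build_analysis_context <- function(records, thresholds = default_thresholds(),
                                   n_boot = 100L, seed = 42L,
                                   outgroup = NULL, tree = NULL,
                                   traits = NULL, run_qc = TRUE) {
  qc <- NULL
  if (run_qc && length(qc_marker_set(records))) {
    qc <- filter_dataset(records, thresholds)
    records <- qc$kept
  }
  core <- build_core_alignment(records, thresholds$identity_threshold)
  if (is.null(tree)) {
    raw <- bootstrap_support(core$alignment, n_replicates = n_boot,
                             seed = seed, level = "protein")
    tree_full <- root_and_collapse(raw, outgroup, support_collapse = 0,
                                   prune_outgroup = !is.null(outgroup))
    tree_coll <- root_and_collapse(raw, outgroup,
                                   support_collapse =
                                     thresholds$support_collapse,
                                   prune_outgroup = !is.null(outgroup))
  } else {
    tree_full <- tree
    tree_coll <- collapse_low_support(tree, thresholds$support_collapse)
  }
  genus_of <- vapply(records, function(r) r$genus, character(1))
  species_of <- vapply(records, function(r) r$species, character(1))
  type_of <- vapply(records, function(r) r$is_type_species, logical(1))
  year_of <- tapply(vapply(records, function(r) r$genus_year, numeric(1)),
                    genus_of, min)
  phyly <- lapply(setNames(unique(genus_of), unique(genus_of)), function(g) {
    classify_group(tree_coll, intersect(names(genus_of)[genus_of == g],
                                        tree_coll$tip.label))
  })
  if (is.null(traits)) traits <- trait_profiles(records,
                                                thresholds$nacl_high)
  ctx <- list(records = records, thresholds = thresholds,
              cache = new_metric_cache(),
              alignment = core$alignment, clusters = core$clusters,
              tree = tree_coll, tree_full = tree_full,
              pd = patristic_matrix(tree_full),
              cp = cp_similarity_matrices(core$alignment),
              genus_of = genus_of, species_of = species_of,
              type_of = type_of, year_of = as.list(year_of),
              phyly = phyly, traits = traits, qc = qc, seed = seed)
  class(ctx) <- "analysis_context"
  ctx
}

#' @export
print.analysis_context <- function(x, ...) {
  st <- table(vapply(x$phyly, function(r) r$status, character(1)))
  cat("<analysis_context>", length(x$records), "strains,",
      nrow(x$alignment$blocks), "core genes,",
      paste(names(st), st, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full taxonomic revision and emit proposals
#'
#' Applies, in order: the species rules within every monophyletic genus
#' context (for non-monophyletic genera only strains of the same pure clade
#' are compared), the genus outlier scan over monophyletic genera, the
#' paraphyly and polyphyly resolutions, and the family-level split test.
#' The family split is only proposed when the claimed family labels do not
#' already separate the two major lineages.
#'
#' @param ctx an `analysis_context`, or a named list of strain records (in
#'   which case the context is built with the remaining arguments).
#' @param ... passed to [build_analysis_context()] when `ctx` is a record
#'   list.
#' @return list with `proposals` (data.frame), `reference`
#'   (the [reference_distributions()]), `family_tests` and the context.
#' @export
revise_taxonomy <- function(ctx, ...) {
  if (!inherits(ctx, "analysis_context")) {
    ctx <- build_analysis_context(ctx, ...)
  }
  ref <- reference_distributions(ctx, seed = ctx$seed)
  proposals <- empty_proposals()
  statuses <- vapply(ctx$phyly, function(r) r$status, character(1))
  # species level: within each monophyletic context
  for (g in names(ctx$phyly)) {
    contexts <- if (statuses[[g]] == "monophyletic") {
      list(names(ctx$genus_of)[ctx$genus_of == g])
    } else {
      ctx$phyly[[g]]$pure_clades
    }
    for (tips in contexts) {
      prs <- all_pairs(tips)
      for (r in seq_len(nrow(prs))) {
        a <- prs[r, 1]; b <- prs[r, 2]
        if (ctx$species_of[[a]] == ctx$species_of[[b]]) next
        p <- species_decision(ctx, a, b)
        if (!is.null(p)) proposals <- rbind(proposals, p)
      }
    }
  }
  # genus level
  for (g in names(statuses)[statuses == "monophyletic"]) {
    proposals <- rbind(proposals, genus_outlier_scan(ctx, g, ref))
  }
  for (g in names(statuses)[statuses == "paraphyletic"]) {
    proposals <- rbind(proposals, resolve_paraphyly(ctx, g, ref))
  }
  for (g in names(statuses)[statuses == "polyphyletic"]) {
    proposals <- rbind(proposals, resolve_polyphyly(ctx, g, ref))
  }
  proposals <- unique(proposals)
  # family level
  family_tests <- NULL
  lineages <- tryCatch(
    two_major_lineages(ctx$tree,
                       support_min = ctx$thresholds$family_support_min,
                       coverage_min = ctx$thresholds$family_coverage_min),
    error = function(e) NULL)
  if (!is.null(lineages)) {
    fam_of <- vapply(ctx$records, function(r) r$family, character(1))
    already_split <- length(unique(stats::na.omit(fam_of))) >= 2L &&
      length(unique(stats::na.omit(fam_of[lineages$a]))) == 1L &&
      length(unique(stats::na.omit(fam_of[lineages$b]))) == 1L &&
      !identical(unique(stats::na.omit(fam_of[lineages$a])),
                 unique(stats::na.omit(fam_of[lineages$b])))
    fam <- family_split_test(ctx, lineages, seed = ctx$seed)
    family_tests <- fam$tests
    if (!already_split && !is.null(fam$proposal)) {
      proposals <- rbind(proposals, fam$proposal)
    }
  }
  list(proposals = proposals, reference = ref,
       family_tests = family_tests, lineages = lineages, context = ctx)
}

#' Place a new genome against a reference dataset
#'
#' The shortlist workflow: the query's AAI against every reference strain
#' picks the k closest relatives, augmented with the claimed genus' type
#' species and representatives; a core-genome NJ subtree is inferred on the
#' shortlist; monophyly of query + claimed genus is checked; and a species
#' assignment is made when one reference passes both species thresholds.
#'
#' @param query a [strain_record()].
#' @param reference named list of strain records.
#' @param k shortlist size (default 10).
#' @param thresholds a [default_thresholds()] list.
#' @param claimed_genus genus the query is proposed to belong to; defaults
#'   to the query's own genus field when present among the references.
#' @return a `placement_report` list: shortlist with AAI values, subtree,
#'   `genus_confirmed`, `species_assignment`, `recommendation`.
#' @export
place_new_genome <- function(query, reference,
                             k = default_thresholds()$shortlist_k,
                             thresholds = default_thresholds(),
                             claimed_genus = NULL) {
  stopifnot(k >= 1)
  cache <- new_metric_cache()
  aai_all <- vapply(reference, function(r) aai(query, r, thresholds, cache),
                    numeric(1))
  if (all(is.na(aai_all))) stop("no computable AAI against the reference")
  top <- names(sort(aai_all, decreasing = TRUE))[seq_len(min(k,
                                                             length(aai_all)))]
  ref_genus <- vapply(reference, function(r) r$genus, character(1))
  if (is.null(claimed_genus)) {
    claimed_genus <- if (query$genus %in% ref_genus) query$genus
    else ref_genus[[top[1]]]
  }
  shortlist <- union(top, names(reference)[ref_genus == claimed_genus])
  subtree_records <- c(reference[shortlist], list(query))
  names(subtree_records)[length(subtree_records)] <- query$strain_id
  subtree <- tryCatch({
    core <- build_core_alignment(subtree_records,
                                 thresholds$identity_threshold)
    D <- distance_matrix(core$alignment, "protein")
    phangorn::midpoint(neighbor_joining(D))
  }, error = function(e) NULL)
  genus_tips <- intersect(names(reference)[ref_genus == claimed_genus],
                          shortlist)
  genus_confirmed <- FALSE
  if (!is.null(subtree) && length(genus_tips)) {
    rep <- classify_group(subtree, c(genus_tips, query$strain_id))
    genus_confirmed <- rep$status == "monophyletic"
  }
  species_assignment <- NA_character_
  best <- top[1]
  m <- ani_dddh(query, reference[[best]], thresholds, cache)
  if (!is.na(m$ani) && !is.na(m$dddh) &&
      m$ani >= thresholds$ani_species && m$dddh >= thresholds$dddh_species) {
    species_assignment <- reference[[best]]$species
  }
  recommendation <- if (genus_confirmed) {
    paste0("query placed within genus ", claimed_genus)
  } else {
    "no genus confirmed; run a full analysis with more representatives"
  }
  structure(list(shortlist = data.frame(strain_id = shortlist,
                                        aai = aai_all[shortlist],
                                        genus = ref_genus[shortlist],
                                        stringsAsFactors = FALSE),
                 shortlist_size = length(shortlist),
                 subtree = subtree, claimed_genus = claimed_genus,
                 genus_confirmed = genus_confirmed,
                 best_hit = best, best_ani = m$ani, best_dddh = m$dddh,
                 species_assignment = species_assignment,
                 recommendation = recommendation),
            class = "placement_report")
}

#' @export
print.placement_report <- function(x, ...) {
  cat("<placement_report> claimed genus:", x$claimed_genus,
      if (x$genus_confirmed) "(confirmed)" else "(not confirmed)", "\n")
  cat("  shortlist:", x$shortlist_size, "strains; best hit", x$best_hit,
      sprintf("(AAI %.1f)\n", x$shortlist$aai[1]))
  if (!is.na(x$species_assignment)) {
    cat("  species assignment:", x$species_assignment, "\n")
  }
  invisible(x)
}

#' Match proposals against a truth ledger
#'
#' @param proposals proposal data.frame from [revise_taxonomy()].
#' @param ledger truth ledger from the injection engine.
#' @return logical vector, one per ledger row: a proposal with the expected
#'   action, subjects and (when stated) destination exists.
#' @export
match_proposals <- function(proposals, ledger) {
  vapply(seq_len(nrow(ledger)), function(i) {
    l <- ledger[i, ]
    hit <- proposals$action == l$expected_action &
      proposals$subjects == l$expected_subjects
    if (!is.na(l$expected_destination) &&
        l$expected_action != "new_genus") {
      hit <- hit & proposals$destination == l$expected_destination
    }
    any(hit)
  }, logical(1))
}
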