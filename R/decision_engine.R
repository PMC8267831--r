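# Species-, genus- and family-level decision rules applied to metrics +
# phyly reports, emitting an auditable list of reclassification proposals.
#
# Rules implemented (priority rules of prokaryotic nomenclature):
#  - species: same species iff dDDH >= 70 AND ANI >= 95 AND monophyletic;
#    recorded phenotype differences demote the merge to a subspecies
#    proposal.
#  - paraphyly: the first described ("primary") genus retains its name; the
#    resolution with the fewest species name changes among those whose
#    metrics sit in the within-genus reference range wins.
#  - polyphyly: the clade containing the type species ("primary clade")
#    retains the name; other pure clades are merged with their nearest
#    neighbor or given a new genus placeholder, with phenotype counts
#    breaking metric ties.
#  - family: a split is proposed when both major lineages are strongly
#    supported and all genomic metrics separate within- from
#    between-lineage comparisons.

proposal_row <- function(action, subjects, destination = NA_character_,
                         name_changes = 0L, evidence = list(),
                         group = NA_character_) {
  ev <- paste(names(evidence),
              vapply(evidence, function(x) paste(format(x, digits = 4),
                                                 collapse = ","),
                     character(1)),
              sep = "=", collapse = "; ")
  data.frame(action = action,
             subjects = paste(sort(subjects), collapse = ";"),
             destination = destination,
             name_changes = as.integer(name_changes),
             group = group, evidence = ev, stringsAsFactors = FALSE)
}

empty_proposals <- function() {
  data.frame(action = character(), subjects = character(),
             destination = character(), name_changes = integer(),
             group = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

# ---- analysis context -------------------------------------------------------

# memoized pairwise getters; keys are sorted strain-id pairs
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

ctx_aai <- function(ctx, a, b) {
  cache_get(ctx$cache, paste0("aai_", pair_key(a, b)), function() {
    aai(ctx$records[[a]], ctx$records[[b]], ctx$thresholds, ctx$cache)
  })
}

ctx_ani_dddh <- function(ctx, a, b) {
  cache_get(ctx$cache, paste0("ad_", pair_key(a, b)), function() {
    ani_dddh(ctx$records[[a]], ctx$records[[b]], ctx$thresholds, ctx$cache)
  })
}

ctx_pd <- function(ctx, a, b) ctx$pd[a, b]
ctx_cp <- function(ctx, a, b) {
  c(cp1 = ctx$cp$cp1[a, b], cp2 = ctx$cp$cp2[a, b], cp3 = ctx$cp$cp3[a, b])
}

all_pairs <- function(v) {
  if (length(v) < 2L) return(matrix(character(), 0, 2))
  t(combn(sort(v), 2L))
}

cross_pairs <- function(u, v) {
  as.matrix(expand.grid(a = u, b = v, stringsAsFactors = FALSE))
}

#' Reference distributions of within- and between-genus metric values
#'
#' Built only from genera whose phyly status is monophyletic, as the
#' published procedure prescribes.  PD and codon-position similarities use
#' every pair; AAI (the expensive metric) uses every within-genus pair and a
#' seeded subsample of at most `max_between_pairs` between-genus pairs.
#'
#' @param ctx analysis context from [build_analysis_context()].
#' @param max_between_pairs cap on sampled between-genus AAI pairs.
#' @param seed seed for the subsample.
#' @return a `reference_distributions` object with `within`/`between` value
#'   multisets and `[min, max]` (or quantile) ranges per metric.
#' @export
reference_distributions <- function(ctx, max_between_pairs =
                                      ctx$thresholds$max_between_pairs,
                                    seed = 42L) {
  mono <- names(ctx$phyly)[vapply(ctx$phyly, function(r)
    r$status == "monophyletic", logical(1))]
  mono_tips <- lapply(mono, function(g) names(ctx$genus_of)[
    ctx$genus_of == g])
  names(mono_tips) <- mono
  multi <- mono[lengths(mono_tips) >= 2L]
  if (!length(multi)) stop("no monophyletic genus with >= 2 strains")
  wpairs <- do.call(rbind, lapply(multi, function(g)
    all_pairs(mono_tips[[g]])))
  bpairs <- do.call(rbind, unlist(lapply(seq_along(mono), function(i) {
    lapply(seq_along(mono)[-seq_len(i)], function(j) {
      cross_pairs(mono_tips[[i]], mono_tips[[j]])
    })
  }), recursive = FALSE))
  set.seed(seed)
  b_aai <- bpairs[sample.int(nrow(bpairs),
                             min(max_between_pairs, nrow(bpairs))), ,
                  drop = FALSE]
  vals <- function(pairs, metric) {
    if (!nrow(pairs)) return(numeric())
    switch(metric,
      aai = vapply(seq_len(nrow(pairs)), function(r)
        ctx_aai(ctx, pairs[r, 1], pairs[r, 2]), numeric(1)),
      pd = ctx$pd[pairs],
      cp1 = ctx$cp$cp1[pairs], cp2 = ctx$cp$cp2[pairs],
      cp3 = ctx$cp$cp3[pairs])
  }
  metrics <- c("aai", "pd", "cp1", "cp2", "cp3")
  within <- lapply(setNames(metrics, metrics), function(m) vals(wpairs, m))
  between <- lapply(setNames(metrics, metrics), function(m)
    vals(if (m == "aai") b_aai else bpairs, m))
  mode <- ctx$thresholds$ref_mode
  q <- ctx$thresholds$ref_quantile
  ranges <- lapply(setNames(metrics, metrics), function(m) {
    w <- within[[m]][!is.na(within[[m]])]
    if (mode == "quantile") quantile(w, q, names = FALSE)
    else range(w)
  })
  tests <- lapply(setNames(metrics, metrics), function(m) {
    w <- within[[m]][!is.na(within[[m]])]
    b <- between[[m]][!is.na(between[[m]])]
    if (length(w) && length(b)) mann_whitney_u(w, b, mode = "normal")
    else NULL
  })
  structure(list(within = within, between = between, ranges = ranges,
                 tests = tests, mono_genera = mono,
                 n_within_pairs = nrow(wpairs),
                 n_between_pairs = nrow(bpairs)),
            class = "reference_distributions")
}

# is `value` inside the within-genus range / clearly on the between side?
ref_within <- function(ref, metric, value) {
  r <- ref$ranges[[metric]]
  !is.na(value) && value >= r[1] && value <= r[2]
}

ref_between_side <- function(ref, metric, value) {
  r <- ref$ranges[[metric]]
  if (is.na(value)) return(FALSE)
  if (metric == "pd") value > r[2] else value < r[1]
}

# count phenotype differences between two tip groups: traits whose
# group-positive fractions differ by at least 0.5
trait_diff_count <- function(ctx, tips_a, tips_b) {
  if (is.null(ctx$traits)) return(NA_integer_)
  tr <- ctx$traits
  traits <- intersect(c("dmsp_demethylation", "dmsp_cleavage", "ahl_qs",
                        "high_salinity"), names(tr))
  n <- 0L
  for (t in traits) {
    va <- tr[[t]][match(tips_a, tr$strain_id)]
    vb <- tr[[t]][match(tips_b, tr$strain_id)]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (!length(va) || !length(vb)) next
    if (abs(mean(va) - mean(vb)) >= 0.5) n <- n + 1L
  }
  n
}

# ---- species level ----------------------------------------------------------

#' Species-level decision for one strain pair
#'
#' Same species iff dDDH and ANI meet their thresholds and the pair is
#' monophyletic on the (collapsed) tree within its claimed species context;
#' a recorded phenotype difference demotes the merge to subspecies rank.
#'
#' @param ctx analysis context.
#' @param a,b strain ids with distinct claimed species.
#' @return one-row proposal data.frame, or NULL.
#' @export
species_decision <- function(ctx, a, b) {
  m <- ctx_ani_dddh(ctx, a, b)
  th <- ctx$thresholds
  if (is.na(m$dddh) || is.na(m$ani)) {
    return(proposal_row("flag_inconclusive", c(a, b),
                        evidence = list(reason = "missing metric"),
                        group = ctx$genus_of[[a]]))
  }
  if (m$dddh < th$dddh_species || m$ani < th$ani_species) return(NULL)
  species_tips <- names(ctx$species_of)[
    ctx$species_of %in% c(ctx$species_of[[a]], ctx$species_of[[b]])]
  mono <- classify_group(ctx$tree, intersect(species_tips,
                                             ctx$tree$tip.label))
  if (mono$status != "monophyletic") return(NULL)
  nd <- trait_diff_count(ctx, a, b)
  dest <- sort(c(ctx$species_of[[a]], ctx$species_of[[b]]))[1]
  action <- if (!is.na(nd) && nd >= 1L) "demote_to_subspecies"
  else "merge_species"
  proposal_row(action, c(a, b), destination = dest, name_changes = 1L,
               evidence = list(dddh = m$dddh, ani = m$ani,
                               trait_diffs = nd),
               group = ctx$genus_of[[a]])
}

# ---- genus level ------------------------------------------------------------

#' Scan a monophyletic genus for genomic outliers
#'
#' For each within-genus pair, all of AAI, PD and the three codon-position
#' similarities are compared to the within-genus reference range.  All five
#' on the between-genus side: the non-type member is proposed as a new
#' genus; a partial signal is flagged inconclusive; otherwise nothing.
#'
#' @param ctx analysis context.
#' @param genus claimed genus token (monophyletic, >= 2 strains).
#' @param ref reference distributions.
#' @return proposal data.frame (possibly empty).
#' @export
genus_outlier_scan <- function(ctx, genus, ref) {
  if (is.null(ref)) stop("empty reference distributions")
  tips <- names(ctx$genus_of)[ctx$genus_of == genus]
  if (length(tips) < 2L) return(empty_proposals())
  pairs <- all_pairs(tips)
  out <- empty_proposals()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    vals <- c(aai = ctx_aai(ctx, a, b), pd = ctx_pd(ctx, a, b),
              ctx_cp(ctx, a, b))
    side <- vapply(names(vals), function(m)
      ref_between_side(ref, m, vals[[m]]), logical(1))
    if (all(side)) {
      others <- setdiff(tips, c(a, b))
      cand <- if (ctx$type_of[[a]]) b
      else if (ctx$type_of[[b]]) a
      else if (length(others)) {
        # the member farther from the rest of the genus
        if (mean(ctx$pd[a, others]) > mean(ctx$pd[b, others])) a else b
      } else b
      out <- rbind(out, proposal_row(
        "new_genus", cand, destination = new_genus_name(ctx),
        name_changes = 1L,
        evidence = as.list(vals), group = genus))
    } else if (any(side)) {
      out <- rbind(out, proposal_row(
        "flag_inconclusive", c(a, b),
        evidence = c(as.list(vals),
                     list(outside = paste(names(vals)[side],
                                          collapse = ","))),
        group = genus))
    }
  }
  unique(out)
}

new_genus_name <- function(ctx) {
  n <- (ctx$cache$novel_count %||% 0L) + 1L
  ctx$cache$novel_count <- n
  sprintf("NovelGenus_%02d", n)
}

# claimed genus of the nearest (patristic) tip outside `tips`
nearest_genus <- function(ctx, tips, exclude_genus = NULL) {
  pool <- setdiff(rownames(ctx$pd), tips)
  if (!is.null(exclude_genus)) {
    pool <- pool[!(ctx$genus_of[pool] %in% exclude_genus)]
  }
  if (!length(pool)) return(NA_character_)
  sub <- ctx$pd[tips, pool, drop = FALSE]
  ctx$genus_of[[pool[which.min(apply(sub, 2, min))]]]
}

# are all cross-pair AAI and PD values inside the within-genus range?
pairs_within_range <- function(ctx, ref, tips_a, tips_b) {
  pr <- cross_pairs(tips_a, tips_b)
  vals_aai <- vapply(seq_len(nrow(pr)), function(r)
    ctx_aai(ctx, pr[r, 1], pr[r, 2]), numeric(1))
  vals_pd <- ctx$pd[pr]
  list(ok = all(vapply(vals_aai, ref_within, logical(1), ref = ref,
                       metric = "aai")) &&
         all(vapply(vals_pd, ref_within, logical(1), ref = ref,
                    metric = "pd")),
       between = all(vapply(vals_aai, ref_between_side, logical(1),
                            ref = ref, metric = "aai")) &&
         all(vapply(vals_pd, ref_between_side, logical(1), ref = ref,
                    metric = "pd")),
       aai = vals_aai, pd = vals_pd)
}

#' Resolve a paraphyletic genus
#'
#' Candidate resolutions are enumerated: merge every genus of the conflict
#' clade into the primary (earliest described) genus, or transfer the
#' minimal set of misplaced tips to the genus that surrounds them.  Each
#' candidate is scored by metric compatibility (AAI and PD inside the
#' within-genus reference range) and by the number of species name changes;
#' the compatible candidate with the fewest changes wins.
#'
#' @param ctx analysis context.
#' @param genus the paraphyletic claimed genus.
#' @param ref reference distributions.
#' @return proposal data.frame.
#' @export
resolve_paraphyly <- function(ctx, genus, ref) {
  report <- ctx$phyly[[genus]]
  stopifnot(report$status == "paraphyletic")
  clade_tips <- report$mrca_tips
  clade_genera <- unique(ctx$genus_of[clade_tips])
  years <- vapply(clade_genera, function(g) ctx$year_of[[g]], numeric(1))
  primary <- clade_genera[order(years, clade_genera)][1]
  candidates <- list()
  # (a) merge the whole clade into the primary genus
  moved <- clade_tips[ctx$genus_of[clade_tips] != primary]
  keep_tips <- setdiff(clade_tips, moved)
  fit <- pairs_within_range(ctx, ref, moved, keep_tips)
  candidates[[1]] <- list(
    rows = proposal_row("merge_genus", moved, destination = primary,
                        name_changes = length(moved),
                        evidence = list(aai = range(fit$aai),
                                        pd = range(fit$pd),
                                        primary = primary),
                        group = genus),
    ok = fit$ok, changes = length(moved), order = 2L)
  # (b) transfer the non-primary pure clades of the genus to the genus that
  #     surrounds each of them
  type_tip <- names(ctx$type_of)[ctx$type_of & ctx$genus_of == genus]
  prim_idx <- if (length(type_tip)) {
    tryCatch(find_primary_clade(report, type_tip[1]), error = function(e) 1L)
  } else 1L
  move_clades <- report$pure_clades[-prim_idx]
  if (length(move_clades)) {
    rows <- empty_proposals()
    ok <- TRUE; changes <- 0L
    for (cl in move_clades) {
      dest <- nearest_genus(ctx, cl, exclude_genus = genus)
      dest_tips <- names(ctx$genus_of)[ctx$genus_of == dest]
      fit <- pairs_within_range(ctx, ref, cl, dest_tips)
      ok <- ok && fit$ok && !is.na(dest)
      changes <- changes + length(cl)
      rows <- rbind(rows, proposal_row(
        "transfer_species", cl, destination = dest,
        name_changes = length(cl),
        evidence = list(aai = range(fit$aai), pd = range(fit$pd)),
        group = genus))
    }
    candidates[[2]] <- list(rows = rows, ok = ok, changes = changes,
                            order = 1L)
  }
  ok_cand <- Filter(function(cd) cd$ok, candidates)
  if (!length(ok_cand)) {
    return(proposal_row("flag_inconclusive", clade_tips,
                        evidence = list(reason =
                                          "no metric-compatible resolution"),
                        group = genus))
  }
  pick <- ok_cand[[order(vapply(ok_cand, function(cd) cd$changes,
                                numeric(1)),
                         vapply(ok_cand, function(cd) cd$order,
                                numeric(1)))[1]]]
  pick$rows
}

#' Resolve a polyphyletic genus
#'
#' The pure clade containing the type species retains the genus name.  Every
#' other pure clade is compared to its nearest-neighbor genus: metrics
#' inside the within-genus range and few phenotype differences merge it into
#' that neighbor; metrics clearly on the between-genus side make it a new
#' genus; otherwise the phenotype difference count decides (and the evidence
#' records that phenotype was decisive).
#'
#' @param ctx analysis context.
#' @param genus the polyphyletic claimed genus.
#' @param ref reference distributions.
#' @return proposal data.frame.
#' @export
resolve_polyphyly <- function(ctx, genus, ref) {
  report <- ctx$phyly[[genus]]
  stopifnot(report$status == "polyphyletic")
  type_tip <- names(ctx$type_of)[ctx$type_of & ctx$genus_of == genus]
  if (!length(type_tip)) stop("type species of ", genus, " not located")
  prim_idx <- find_primary_clade(report, type_tip[1])
  out <- empty_proposals()
  limit <- ctx$thresholds$trait_diff_limit
  for (idx in setdiff(seq_along(report$pure_clades), prim_idx)) {
    cl <- report$pure_clades[[idx]]
    dest <- nearest_genus(ctx, cl, exclude_genus = genus)
    dest_tips <- names(ctx$genus_of)[ctx$genus_of == dest]
    fit <- pairs_within_range(ctx, ref, cl, dest_tips)
    nd <- trait_diff_count(ctx, cl, dest_tips)
    ev <- list(aai = range(fit$aai), pd = range(fit$pd), neighbor = dest,
               trait_diffs = nd)
    if (fit$ok && (!is.na(nd) && nd < limit)) {
      out <- rbind(out, proposal_row("merge_genus", cl, destination = dest,
                                     name_changes = length(cl),
                                     evidence = ev, group = genus))
    } else if (fit$between) {
      out <- rbind(out, proposal_row("new_genus", cl,
                                     destination = new_genus_name(ctx),
                                     name_changes = length(cl),
                                     evidence = ev, group = genus))
    } else if (is.na(nd)) {
      out <- rbind(out, proposal_row("flag_inconclusive", cl,
                                     evidence = c(ev, list(
                                       reason = "no trait table")),
                                     group = genus))
    } else if (nd >= limit) {
      ev$phenotype_decisive <- TRUE
      out <- rbind(out, proposal_row("new_genus", cl,
                                     destination = new_genus_name(ctx),
                                     name_changes = length(cl),
                                     evidence = ev, group = genus))
    } else {
      ev$phenotype_decisive <- TRUE
      out <- rbind(out, proposal_row("merge_genus", cl, destination = dest,
                                     name_changes = length(cl),
                                     evidence = ev, group = genus))
    }
  }
  out
}

# ---- family level -----------------------------------------------------------

#' Test whether the two major lineages deserve separate families
#'
#' Mann-Whitney U comparisons of within- versus between-lineage PD, AAI and
#' codon-position similarities.  A family split is proposed iff both
#' lineages are monophyletic with strong support and all tests are
#' significant in the expected direction (within < between for PD, within >
#' between for similarities).
#'
#' @param ctx analysis context.
#' @param lineages list with tip sets `a` and `b` (see
#'   [two_major_lineages()]).
#' @param alpha significance level.
#' @param max_pairs cap on sampled AAI pairs per stratum.
#' @param seed subsample seed.
#' @return list with `proposal` (row or NULL) and the per-metric `tests`.
#' @export
family_split_test <- function(ctx, lineages, alpha = ctx$thresholds$alpha,
                              max_pairs = ctx$thresholds$max_between_pairs,
                              seed = 42L) {
  a <- intersect(lineages$a, rownames(ctx$pd))
  b <- intersect(lineages$b, rownames(ctx$pd))
  if (length(a) < 2L || length(b) < 2L) stop("each lineage needs >= 2 tips")
  supp_ok <- vapply(list(a, b), function(tp) {
    nd <- mrca_node(ctx$tree, intersect(tp, ctx$tree$tip.label))
    s <- node_support(ctx$tree)[nd - length(ctx$tree$tip.label)]
    rep <- classify_group(ctx$tree, intersect(tp, ctx$tree$tip.label))
    rep$status == "monophyletic" &&
      (is.na(s) || s >= ctx$thresholds$family_support_min)
  }, logical(1))
  wpairs <- rbind(all_pairs(a), all_pairs(b))
  bpairs <- cross_pairs(a, b)
  set.seed(seed)
  sub <- function(p) p[sample.int(nrow(p), min(max_pairs, nrow(p))), ,
                       drop = FALSE]
  w_aai_pairs <- sub(wpairs); b_aai_pairs <- sub(bpairs)
  tests <- list()
  ok <- all(supp_ok)
  for (m in c("pd", "cp1", "cp2", "cp3", "aai")) {
    if (m == "aai") {
      w <- vapply(seq_len(nrow(w_aai_pairs)), function(r)
        ctx_aai(ctx, w_aai_pairs[r, 1], w_aai_pairs[r, 2]), numeric(1))
      bv <- vapply(seq_len(nrow(b_aai_pairs)), function(r)
        ctx_aai(ctx, b_aai_pairs[r, 1], b_aai_pairs[r, 2]), numeric(1))
    } else if (m == "pd") {
      w <- ctx$pd[wpairs]; bv <- ctx$pd[bpairs]
    } else {
      w <- ctx$cp[[m]][wpairs]; bv <- ctx$cp[[m]][bpairs]
    }
    w <- w[!is.na(w)]; bv <- bv[!is.na(bv)]
    tst <- mann_whitney_u(w, bv, mode = "normal")
    direction_ok <- if (m == "pd") stats::median(w) < stats::median(bv)
    else stats::median(w) > stats::median(bv)
    tests[[m]] <- c(tst, list(direction_ok = direction_ok))
    ok <- ok && tst$p.value < alpha && direction_ok
  }
  proposal <- if (ok) {
    proposal_row("split_family", c(a, b), destination = "NovelFamily_01",
                 name_changes = length(b),
                 evidence = list(
                   p_max = max(vapply(tests, function(t) t$p.value,
                                      numeric(1))),
                   support_ok = all(supp_ok)))
  } else NULL
  list(proposal = proposal, tests = tests)
}
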