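# Rule-level tests run against a fabricated context with preloaded metric
# caches, so each decision rule is exercised at exact boundary values;
# integration behaviour on simulated data is covered by the acceptance
# suite.

fake_ctx <- function(dddh = NA, ani = NA, pair = c("a", "b"),
                     traits = NULL) {
  tree <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  cache <- new_metric_cache()
  if (!is.na(dddh)) {
    cache[[paste0("ad_", pair_key(pair[1], pair[2]))]] <-
      list(ani = ani, dddh = dddh)
  } else {
    cache[[paste0("ad_", pair_key(pair[1], pair[2]))]] <-
      list(ani = NA_real_, dddh = NA_real_)
  }
  list(thresholds = default_thresholds(), cache = cache, tree = tree,
       genus_of = setNames(rep("gX", 4), letters[1:4]),
       species_of = setNames(paste0("sp_", letters[1:4]), letters[1:4]),
       type_of = setNames(c(TRUE, FALSE, FALSE, FALSE), letters[1:4]),
       traits = traits)
}

test_that("species decisions require dDDH, ANI and monophyly jointly", {
  # dDDH 52.4 with ANI below threshold: different species
  expect_null(species_decision(fake_ctx(52.4, 94), "a", "b"))
  # both thresholds are required, not either
  expect_null(species_decision(fake_ctx(75, 94), "a", "b"))
  expect_null(species_decision(fake_ctx(69.9, 97), "a", "b"))
  # passing metrics but a non-sister pair: no merge
  expect_null(species_decision(fake_ctx(100, 100, pair = c("a", "c")),
                               "a", "c"))
  # passing metrics, sisters, no trait table: plain merge
  p <- species_decision(fake_ctx(100, 100), "a", "b")
  expect_identical(p$action, "merge_species")
  expect_identical(p$subjects, "a;b")
  expect_equal(p$name_changes, 1)
  # recorded trait differences demote to subspecies
  tr <- data.frame(strain_id = c("a", "b"),
                   dmsp_demethylation = c(TRUE, FALSE),
                   dmsp_cleavage = c(TRUE, TRUE),
                   ahl_qs = c(FALSE, FALSE),
                   high_salinity = c(NA, NA), stringsAsFactors = FALSE)
  p2 <- species_decision(fake_ctx(100, 100, traits = tr), "a", "b")
  expect_identical(p2$action, "demote_to_subspecies")
  # missing metric flags the pair
  p3 <- species_decision(fake_ctx(NA, NA), "a", "b")
  expect_identical(p3$action, "flag_inconclusive")
})

test_that("genus outlier scan needs all five metrics on the between side", {
  tips <- c("a", "b")
  pdm <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(pdm) <- 0
  mk_ctx <- function(aai_val, pd_val, cp_vals) {
    cache <- new_metric_cache()
    cache[[paste0("aai_", pair_key("a", "b"))]] <- aai_val
    pdm["a", "b"] <- pdm["b", "a"] <- pd_val
    cp <- lapply(setNames(cp_vals, c("cp1", "cp2", "cp3")), function(v) {
      m <- matrix(v, 4, 4, dimnames = dimnames(pdm)); diag(m) <- 100; m
    })
    list(thresholds = default_thresholds(), cache = cache, pd = pdm,
         cp = cp, genus_of = setNames(c("gX", "gX", "gY", "gY"),
                                      letters[1:4]),
         type_of = setNames(c(TRUE, FALSE, TRUE, FALSE), letters[1:4]))
  }
  ref <- structure(list(ranges = list(aai = c(80, 95), pd = c(0.05, 0.2),
                                      cp1 = c(90, 99), cp2 = c(92, 99),
                                      cp3 = c(70, 95))),
                   class = "reference_distributions")
  # all five outside on the between side: new genus for the non-type member
  out <- genus_outlier_scan(mk_ctx(65, 0.4, c(85, 88, 60)), "gX", ref)
  expect_identical(out$action, "new_genus")
  expect_identical(out$subjects, "b")
  # conflicting metrics: inconclusive
  out2 <- genus_outlier_scan(mk_ctx(85, 0.4, c(85, 95, 80)), "gX", ref)
  expect_identical(out2$action, "flag_inconclusive")
  # everything inside the within range: silence
  out3 <- genus_outlier_scan(mk_ctx(85, 0.1, c(95, 95, 80)), "gX", ref)
  expect_equal(nrow(out3), 0)
})

test_that("an injected paraphyly resolves by the fewest name changes", {
  cfg <- simulation_config(n_tips = 30, n_genes = 25,
                           gene_length_codons = 200, seed = 55,
                           injections = list(n_para = 1))
  sim <- suppressWarnings(simulate_dataset(cfg))
  skip_if(nrow(sim$truth$ledger) == 0, "no feasible event at this seed")
  res <- revise_taxonomy(sim$records, n_boot = 25, seed = 55)
  led <- sim$truth$ledger
  expect_true(all(match_proposals(res$proposals, led)))
  got <- res$proposals[res$proposals$action == "transfer_species", ]
  expect_equal(got$name_changes, 1)
  # the enumerated alternative (merging the genera) costs more changes
  n_from <- sum(vapply(sim$records, function(r)
    r$genus == led$expected_destination, logical(1)))
  expect_gte(n_from, got$name_changes)
})

test_that("family split logic distinguishes real from shuffled lineages", {
  ctx <- small_ctx()
  lin <- two_major_lineages(ctx$tree, support_min = 95, coverage_min = 0.9)
  real <- family_split_test(ctx, lin, seed = 7)
  expect_false(is.null(real$proposal))
  expect_identical(real$proposal$action, "split_family")
  expect_true(all(vapply(real$tests, function(t) t$p.value, numeric(1)) <
                    0.001))
  # permuted lineage labels: the contrast collapses
  set.seed(91)
  nulls <- 0L
  all_tips <- c(lin$a, lin$b)
  for (perm in 1:10) {
    shuf <- sample(all_tips)
    plin <- list(a = shuf[seq_along(lin$a)],
                 b = shuf[-seq_along(lin$a)])
    got <- family_split_test(ctx, plin, seed = perm)
    if (is.null(got$proposal)) nulls <- nulls + 1L
  }
  expect_gte(nulls, 8)
})

test_that("revise_taxonomy does not re-propose an already split family", {
  sim <- small_sim()
  res <- revise_taxonomy(small_ctx())
  expect_false(any(res$proposals$action == "split_family"))
  # strip the claimed family labels: now the split is proposed
  rec2 <- lapply(sim$records, function(r) { r$family <- NA_character_; r })
  ctx2 <- build_analysis_context(as_dataset(rec2), n_boot = 25, seed = 7)
  res2 <- revise_taxonomy(ctx2)
  expect_true(any(res2$proposals$action == "split_family"))
})

test_that("placement confirms an in-genus query and flags a basal one", {
  sim <- small_sim()
  genus_of <- vapply(sim$records, function(r) r$genus, character(1))
  big_genus <- names(which.max(table(genus_of)))
  member <- names(genus_of)[genus_of == big_genus][1]
  query <- sim$records[[member]]
  query$strain_id <- "query"
  query$genes$gene_id <- sub(member, "query", query$genes$gene_id)
  names(query$genome) <- "query"
  reference <- sim$records[names(sim$records) != member]
  rep <- place_new_genome(query, reference)
  expect_lt(rep$shortlist_size, 20)
  expect_true(any(rep$shortlist$genus == big_genus))
  expect_true(rep$genus_confirmed)
  # identical to a reference strain: species assignment at ANI = dDDH = 100
  query2 <- sim$records[[member]]
  query2$strain_id <- "query2"
  names(query2$genome) <- "query2"
  rep2 <- place_new_genome(query2, sim$records)
  expect_identical(rep2$best_hit, member)
  expect_equal(rep2$best_ani, 100)
  expect_equal(rep2$best_dddh, 100)
  expect_identical(rep2$species_assignment, sim$records[[member]]$species)
  # a basal, long-branch query is not confirmed
  bs <- basal_sim()
  bq <- bs$records[["b01"]]
  ref3 <- bs$records[names(bs$records) != "b01"]
  rep3 <- place_new_genome(bq, ref3)
  expect_false(rep3$genus_confirmed)
  expect_match(rep3$recommendation, "full analysis")
  expect_error(place_new_genome(bq, ref3, k = 0), "k >= 1")
})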