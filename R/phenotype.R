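# Marker-gene phenotype prediction and family-level trait contrasts.
# Pathway calls operate on detected homolog counts (marker labels), so the
# detection engine is pluggable: demethylation needs all of dmdA/B/C,
# cleavage any of the six ddd lyases, AHL quorum sensing at least one copy
# each of luxR and luxI.  High salinity is an isolation-metadata call,
# boundary inclusive at 3.5 percent w/v NaCl.

#' Call pathway phenotypes for one strain
#'
#' @param record a [strain_record()].
#' @param nacl_high high-salinity boundary (percent w/v NaCl, inclusive).
#' @return one-row data.frame: strain_id, dmsp_demethylation, dmsp_cleavage,
#'   ahl_qs, high_salinity (NA when salinity is unrecorded), environment.
#' @export
call_pathways <- function(record, nacl_high = 3.5) {
  counts <- table(record$genes$marker_label)
  n_of <- function(m) if (m %in% names(counts)) as.integer(counts[[m]]) else 0L
  data.frame(
    strain_id = record$strain_id,
    dmsp_demethylation = n_of("dmdA") >= 1L && n_of("dmdB") >= 1L &&
      n_of("dmdC") >= 1L,
    dmsp_cleavage = sum(vapply(DDD_GENES, n_of, integer(1))) >= 1L,
    ahl_qs = n_of("luxR") >= 1L && n_of("luxI") >= 1L,
    high_salinity = if (is.na(record$nacl_percent)) NA
    else record$nacl_percent >= nacl_high,
    environment = record$environment,
    stringsAsFactors = FALSE)
}

#' Trait profiles for a whole dataset
#' @param records named list of strain records.
#' @inheritParams call_pathways
#' @export
trait_profiles <- function(records, nacl_high = 3.5) {
  out <- do.call(rbind, lapply(records, call_pathways,
                               nacl_high = nacl_high))
  rownames(out) <- NULL
  out
}

#' Family-level trait contrast
#'
#' Per trait: the proportion positive in each family, a pooled-variance
#' two-proportion z-test, plus per-strain trait-combination frequencies
#' (including the both-DMSP-pathways fraction).
#'
#' @param profiles data.frame from [trait_profiles()].
#' @param family named character vector strain_id -> family label (two
#'   families).
#' @param alpha significance level.
#' @return list with `contrast` (per-trait table), `combinations`
#'   (per-family trait-combination frequencies) and `both_dmsp` (fraction
#'   positive for both DMSP pathways per family).
#' @export
family_trait_contrast <- function(profiles, family, alpha = 0.05) {
  fam <- family[profiles$strain_id]
  fams <- sort(unique(stats::na.omit(fam)))
  if (length(fams) != 2L) stop("need exactly two families")
  keep <- !is.na(fam)
  profiles <- profiles[keep, , drop = FALSE]
  fam <- fam[keep]
  if (!all(table(fam) >= 1L)) stop("each family needs at least one strain")
  traits <- c("dmsp_demethylation", "dmsp_cleavage", "ahl_qs",
              "high_salinity")
  rows <- lapply(traits, function(tr) {
    v <- profiles[[tr]]
    ok <- !is.na(v)
    n1 <- sum(ok & fam == fams[1]); k1 <- sum(v & ok & fam == fams[1])
    n2 <- sum(ok & fam == fams[2]); k2 <- sum(v & ok & fam == fams[2])
    zt <- two_proportion_z(k1, n1, k2, n2)
    data.frame(trait = tr, prop1 = k1 / n1, prop2 = k2 / n2,
               delta = k1 / n1 - k2 / n2, z = zt$z, p.value = zt$p.value,
               significant = zt$p.value < alpha, stringsAsFactors = FALSE)
  })
  contrast <- do.call(rbind, rows)
  names(contrast)[2:3] <- paste0("prop_", fams)
  combo <- paste(ifelse(profiles$dmsp_demethylation, "Dm", ""),
                 ifelse(profiles$dmsp_cleavage, "Cl", ""),
                 ifelse(profiles$ahl_qs, "QS", ""),
                 ifelse(!is.na(profiles$high_salinity) &
                          profiles$high_salinity, "Hs", ""), sep = "")
  combo[combo == ""] <- "none"
  combinations <- as.data.frame.matrix(
    prop.table(table(fam, combo), margin = 1))
  both <- vapply(fams, function(f) {
    sel <- fam == f
    mean(profiles$dmsp_demethylation[sel] & profiles$dmsp_cleavage[sel])
  }, numeric(1))
  list(contrast = contrast, combinations = combinations,
       both_dmsp = both, families = fams)
}

#' Rank traits by how well they distinguish the two families
#'
#' @param contrast result of [family_trait_contrast()].
#' @return data.frame of traits with nonzero proportion difference, ranked
#'   by absolute difference; `indicator` marks the top-ranked trait(s).
#' @export
trait_indicator_summary <- function(contrast) {
  tab <- contrast$contrast
  tab <- tab[abs(tab$delta) > 0, , drop = FALSE]
  if (!nrow(tab)) return(tab)
  tab <- tab[order(-abs(tab$delta)), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$indicator <- abs(tab$delta) >= max(abs(tab$delta)) - 1e-12
  rownames(tab) <- NULL
  tab
}
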