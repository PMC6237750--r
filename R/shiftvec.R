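# Chemical-shift vector analysis of methyl (ILV) peak lists.
#
# A test state is compared against reference "open" and "closed" peak sets:
# the reference vector for each methyl runs from the open to the closed
# resonance position, the experimental vector from open to the test-state
# position, and each resonance is classified as on-pathway toward closure,
# off-pathway, or unchanged from the geometry of the two vectors.

# carbon scaling used for all vector geometry (magnitude, cos theta, delta_n)
CARBON_SCALE <- 0.2514

#' Combined chemical-shift change
#'
#' Combined amide-style chemical-shift difference for a methyl resonance,
#' \eqn{\sqrt{(\Delta\delta_H^2 + \Delta\delta_C^2/4)/2}}, used for the
#' significance filter (a shift is significant when the combined change
#' exceeds the threshold, 0.025 ppm by default).
#'
#' @param d_H,d_C Proton and carbon chemical-shift differences (ppm).
#'   Vectorized; recycled to a common length.
#' @return Combined shift in ppm, non-negative.
#' @examples
#' combined_shift(0.05, 0.2)
#' @export
combined_shift <- function(d_H, d_C) {
  check_finite(d_H, "d_H")
  check_finite(d_C, "d_C")
  sqrt((d_H^2 + d_C^2 / 4) / 2)
}

#' Shift-vector magnitude
#'
#' Magnitude of a methyl shift vector in the scaled (H, 0.2514 C) plane,
#' \eqn{\sqrt{\Delta\delta_H^2 + (0.2514\,\Delta\delta_C)^2}}. This scaling
#' is used for all vector geometry (magnitude, normalized magnitude,
#' cos theta); the combined shift above is used only for significance.
#'
#' @inheritParams combined_shift
#' @return Vector magnitude in ppm, non-negative.
#' @export
shift_vector_magnitude <- function(d_H, d_C) {
  check_finite(d_H, "d_H")
  check_finite(d_C, "d_C")
  sqrt(d_H^2 + (CARBON_SCALE * d_C)^2)
}

#' Normalized shift-vector magnitude
#'
#' Ratio of the experimental vector magnitude to the reference (open to
#' closed) vector magnitude; 1 indicates a shift as large as full closure.
#'
#' @param d_H,d_C Experimental shift vector components (ppm).
#' @param ref_H,ref_C Reference shift vector components (ppm).
#' @param degenerate_tol Reference magnitudes at or below this value (ppm)
#'   are degenerate: the ratio is undefined and `NA` is returned.
#' @return Dimensionless ratio, `NA` where the reference is degenerate.
#' @export
normalized_magnitude <- function(d_H, d_C, ref_H, ref_C,
                                 degenerate_tol = 1e-6) {
  m_exp <- shift_vector_magnitude(d_H, d_C)
  m_ref <- shift_vector_magnitude(ref_H, ref_C)
  ifelse(m_ref <= degenerate_tol, NA_real_, m_exp / m_ref)
}

#' Cosine of the angle between experimental and reference shift vectors
#'
#' Dot product of the experimental and reference vectors in the scaled
#' (H, 0.2514 C) plane divided by the product of their magnitudes. 1 means
#' the test-state resonance moved exactly along the open-to-closed
#' direction; values below the cutoff (0.8) mark off-pathway changes.
#'
#' @inheritParams normalized_magnitude
#' @return Cosine in \[-1, 1\], `NA` where either vector is degenerate.
#' @export
cos_theta <- function(d_H, d_C, ref_H, ref_C, degenerate_tol = 1e-6) {
  m_exp <- shift_vector_magnitude(d_H, d_C)
  m_ref <- shift_vector_magnitude(ref_H, ref_C)
  dot <- d_H * ref_H + CARBON_SCALE^2 * d_C * ref_C
  out <- ifelse(m_exp <= degenerate_tol | m_ref <= degenerate_tol,
                NA_real_, dot / (m_exp * m_ref))
  pmin(1, pmax(-1, out))
}

#' Root-mean-square deviation from full on-pathway closure
#'
#' RMSD of per-resonance (cos theta, delta_n) pairs from (1, 1):
#' \eqn{\sqrt{\sum_i ((1-\cos\theta_i)^2 + (1-\Delta\delta_{n,i})^2)/n}}.
#' Zero means every resonance moved fully to the closed position along the
#' open-to-closed direction.
#'
#' @param cos_theta,delta_n Numeric vectors of equal length, one entry per
#'   chemical-shift measurement.
#' @return A single non-negative number.
#' @export
rmsd_one <- function(cos_theta, delta_n) {
  if (length(cos_theta) == 0L || length(cos_theta) != length(delta_n)) {
    abort("`cos_theta` and `delta_n` must be non-empty and of equal length.")
  }
  check_finite(cos_theta, "cos_theta")
  check_finite(delta_n, "delta_n")
  sqrt(mean((1 - cos_theta)^2 + (1 - delta_n)^2))
}

#' Significance threshold from replicate spectra
#'
#' Estimates the minimum combined shift regarded as significant as a
#' multiple (1.5 by default) of the average per-peak combined shift between
#' replicate spectra of the same sample. With `mode = "within"` all
#' replicate pairs inside each group are averaged; `"between"` averages
#' pairs across the two groups instead.
#'
#' @param replicates List of peak-list tibbles (see [peak_list()]).
#' @param groups Character/factor of the same length assigning each
#'   replicate to an enzyme group; default puts all in one group.
#' @param factor Multiplier applied to the average replicate variability.
#' @param mode `"within"` (default) or `"between"` group pairing.
#' @return Threshold in ppm.
#' @export
significance_threshold <- function(replicates, groups = NULL, factor = 1.5,
                                   mode = c("within", "between")) {
  mode <- match.arg(mode)
  if (!is.list(replicates) || length(replicates) < 2L) {
    abort("`replicates` must be a list of at least two peak lists.")
  }
  groups <- groups %||% rep("all", length(replicates))
  pair_shift <- function(a, b) {
    m <- dplyr::inner_join(a, b, by = c("residue", "methyl"),
                           suffix = c("_a", "_b"))
    if (nrow(m) == 0L) return(NULL)
    combined_shift(m$dH_ppm_a - m$dH_ppm_b, m$dC_ppm_a - m$dC_ppm_b)
  }
  pairs <- list()
  if (mode == "within") {
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) < 2L) next
      cmb <- utils::combn(idx, 2L)
      for (j in seq_len(ncol(cmb))) {
        pairs[[length(pairs) + 1L]] <-
          pair_shift(replicates[[cmb[1L, j]]], replicates[[cmb[2L, j]]])
      }
    }
    if (length(pairs) == 0L) {
      abort("`mode = \"within\"` needs at least one group with >= 2 replicates.")
    }
  } else {
    gs <- unique(groups)
    if (length(gs) != 2L) abort("`mode = \"between\"` needs exactly two groups.")
    for (i in which(groups == gs[1L])) {
      for (j in which(groups == gs[2L])) {
        pairs[[length(pairs) + 1L]] <-
          pair_shift(replicates[[i]], replicates[[j]])
      }
    }
  }
  factor * mean(unlist(pairs))
}

#' Classify one resonance from its combined shift and direction
#'
#' A resonance whose combined shift does not exceed `threshold` is
#' `not_significant` (the rule is strict: exactly at the threshold is not
#' significant). A significant resonance is `on_pathway` when
#' cos theta >= `cos_cutoff` (only values strictly below the cutoff count
#' as off-pathway) and `off_pathway` otherwise. A significant resonance
#' whose reference vector is degenerate (cos theta `NA`) is
#' `reference_degenerate`.
#'
#' @param combined Combined shift (ppm), from [combined_shift()].
#' @param cos_theta Cosine from [cos_theta()]; may be `NA`.
#' @param threshold Significance threshold (ppm), default 0.025.
#' @param cos_cutoff On/off-pathway cutoff, default 0.8.
#' @return Character vector with levels `on_pathway`, `off_pathway`,
#'   `not_significant`, `reference_degenerate`.
#' @export
classify_residue <- function(combined, cos_theta, threshold = 0.025,
                             cos_cutoff = 0.8) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  if (cos_cutoff <= -1 || cos_cutoff >= 1) {
    abort("`cos_cutoff` must lie strictly inside (-1, 1).")
  }
  check_finite(combined, "combined")
  dplyr::case_when(
    combined <= threshold ~ "not_significant",
    is.na(cos_theta) ~ "reference_degenerate",
    cos_theta >= cos_cutoff ~ "on_pathway",
    TRUE ~ "off_pathway"
  )
}

#' Default subdomain map for DNA polymerase beta
#'
#' Residue ranges assigning each position of the 335-residue enzyme to the
#' lyase, thumb, palm or fingers subdomain. The boundaries are configurable;
#' these defaults place the catalytic aspartates (D190/D192/D256) in the
#' palm and the I277/R283 region in the fingers.
#'
#' @return Tibble with columns `subdomain`, `start`, `end`.
#' @export
polb_subdomains <- function() {
  tibble(
    subdomain = c("lyase", "thumb", "palm", "fingers"),
    start = c(1L, 88L, 152L, 263L),
    end = c(87L, 151L, 262L, 335L)
  )
}

assign_subdomain <- function(residue, subdomains) {
  validate_subdomains(subdomains)
  out <- rep(NA_character_, length(residue))
  for (i in seq_len(nrow(subdomains))) {
    hit <- residue >= subdomains$start[i] & residue <= subdomains$end[i]
    out[hit] <- subdomains$subdomain[i]
  }
  if (anyNA(out)) {
    abort(paste0("Residues without a subdomain assignment: ",
                 paste(unique(residue[is.na(out)]), collapse = ", ")))
  }
  out
}

validate_subdomains <- function(subdomains) {
  need <- c("subdomain", "start", "end")
  if (!all(need %in% names(subdomains))) {
    abort("`subdomains` needs columns subdomain, start, end.")
  }
  covered <- unlist(purrr::map2(subdomains$start, subdomains$end, seq))
  if (anyDuplicated(covered)) abort("Subdomain ranges overlap.")
  invisible(subdomains)
}

#' Construct a validated methyl peak list
#'
#' @param x Data frame with columns `residue` (integer, >= 1), `restype`
#'   (one of I, L, V), `methyl` (label distinguishing multiple methyls of
#'   one residue; non-stereospecific duplicates appear as distinct rows),
#'   `dH_ppm` and `dC_ppm` (chemical shifts, ppm).
#' @param state_name Name of the enzyme state the list describes.
#' @return Tibble of class `peak_list` with a `state_name` attribute.
#' @export
peak_list <- function(x, state_name = "state") {
  need <- c("residue", "restype", "methyl", "dH_ppm", "dC_ppm")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    abort(paste0("Peak list lacks columns: ", paste(missing, collapse = ", ")))
  }
  x <- as_tibble(x)[need]
  x$residue <- as.integer(x$residue)
  if (nrow(x) == 0L) abort("Peak list is empty.")
  if (any(x$residue < 1L)) abort("Residue numbers must be >= 1.")
  if (!all(x$restype %in% c("I", "L", "V"))) {
    abort("`restype` must be one of I, L, V.")
  }
  check_finite(x$dH_ppm, "dH_ppm")
  check_finite(x$dC_ppm, "dC_ppm")
  key <- paste(x$residue, x$methyl)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate (residue, methyl) keys: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  attr(x, "state_name") <- state_name
  class(x) <- c("peak_list", class(x))
  x
}

#' Re-reference a peak list to an anchor resonance
#'
#' Subtracts the anchor resonance's shift difference between `peaks` and
#' `reference` from every peak, so the anchor coincides in both lists.
#' Useful when spectra were referenced internally to a resonance that does
#' not move on ligand binding (V221 in this system).
#'
#' @param peaks,reference Peak-list tibbles containing the anchor.
#' @param residue,methyl Key of the anchor resonance.
#' @return `peaks` with shifted `dH_ppm`, `dC_ppm`.
#' @export
rereference_peaks <- function(peaks, reference, residue = 221L,
                              methyl = peaks$methyl[peaks$residue == residue][1]) {
  a <- peaks[peaks$residue == residue & peaks$methyl == methyl, ]
  b <- reference[reference$residue == residue & reference$methyl == methyl, ]
  if (nrow(a) != 1L || nrow(b) != 1L) {
    abort("Anchor resonance not found uniquely in both lists.")
  }
  peaks$dH_ppm <- peaks$dH_ppm - (a$dH_ppm - b$dH_ppm)
  peaks$dC_ppm <- peaks$dC_ppm - (a$dC_ppm - b$dC_ppm)
  peaks
}

#' Compare a test state against open and closed reference states
#'
#' For every methyl resonance present in all three lists, the reference
#' vector (closed minus open) and experimental vector (test minus open) are
#' formed in the scaled (H, 0.2514 C) shift plane; the combined shift,
#' normalized magnitude, cos theta and an on/off-pathway classification are
#' computed per resonance, and closure is summarized globally and per
#' subdomain by the RMSD from (cos theta, delta_n) = (1, 1).
#'
#' @param test,open_ref,closed_ref Peak-list tibbles ([peak_list()] or any
#'   data frame with the same columns).
#' @param subdomains Subdomain map tibble; default [polb_subdomains()].
#' @param threshold Significance threshold on the combined shift (ppm).
#' @param cos_cutoff On/off-pathway cosine cutoff.
#' @param degenerate_tol Reference magnitude (ppm) below which vector
#'   ratios are undefined and the row is excluded from RMSD.
#' @param rmsd_rows `"significant"` (default) restricts RMSD and the
#'   average delta_n / cos theta summaries to significant, non-degenerate
#'   rows; `"all"` uses every non-degenerate matched row.
#' @return Object of class `state_comparison`: list with `rows` (per-peak
#'   tibble), `rmsd_global`, `rmsd_by_subdomain`, `counts`, `summary` and
#'   the state names. `tidy()`, `glance()` and `autoplot()` methods exist.
#' @examples
#' sc <- gen_peak_lists(landscape_scenario(closure_fraction = 0.5, seed = 1))
#' cmp <- compare_states(sc$test, sc$open, sc$closed)
#' glance(cmp)
#' @export
compare_states <- function(test, open_ref, closed_ref,
                           subdomains = polb_subdomains(),
                           threshold = 0.025, cos_cutoff = 0.8,
                           degenerate_tol = 1e-6,
                           rmsd_rows = c("significant", "all")) {
  rmsd_rows <- match.arg(rmsd_rows)
  join <- function(a, b, suf) {
    dplyr::inner_join(as_tibble(a), as_tibble(b), by = c("residue", "methyl"),
                      suffix = c("", suf))
  }
  m <- join(join(as_tibble(test), as_tibble(open_ref), "_open"),
            as_tibble(closed_ref), "_closed")
  if (nrow(m) == 0L) abort("No common (residue, methyl) peaks across the three lists.")
  n_unmatched <- nrow(test) - nrow(m)

  rows <- tibble(
    residue = m$residue,
    restype = m$restype,
    methyl = m$methyl,
    subdomain = assign_subdomain(m$residue, subdomains),
    exp_dH = m$dH_ppm - m$dH_ppm_open,
    exp_dC = m$dC_ppm - m$dC_ppm_open,
    ref_dH = m$dH_ppm_closed - m$dH_ppm_open,
    ref_dC = m$dC_ppm_closed - m$dC_ppm_open
  )
  rows$combined_shift <- combined_shift(rows$exp_dH, rows$exp_dC)
  rows$magnitude <- shift_vector_magnitude(rows$exp_dH, rows$exp_dC)
  rows$delta_n <- normalized_magnitude(rows$exp_dH, rows$exp_dC,
                                       rows$ref_dH, rows$ref_dC,
                                       degenerate_tol)
  rows$cos_theta <- cos_theta(rows$exp_dH, rows$exp_dC,
                              rows$ref_dH, rows$ref_dC, degenerate_tol)
  ref_degen <- shift_vector_magnitude(rows$ref_dH, rows$ref_dC) <= degenerate_tol
  cos_for_class <- ifelse(ref_degen, NA_real_, rows$cos_theta)
  rows$classification <- classify_residue(rows$combined_shift, cos_for_class,
                                          threshold, cos_cutoff)

  eligible <- !ref_degen & !is.na(rows$delta_n) & !is.na(rows$cos_theta)
  use <- if (rmsd_rows == "significant") {
    eligible & rows$classification %in% c("on_pathway", "off_pathway")
  } else eligible

  rmsd_global <- if (any(use)) {
    rmsd_one(rows$cos_theta[use], rows$delta_n[use])
  } else NA_real_
  rmsd_by_subdomain <- if (any(use)) {
    rows[use, ] |>
      dplyr::group_by(.data$subdomain) |>
      dplyr::summarise(
        n = dplyr::n(),
        rmsd = rmsd_one(.data$cos_theta, .data$delta_n),
        .groups = "drop"
      )
  } else {
    tibble(subdomain = character(), n = integer(), rmsd = numeric())
  }
  counts <- rows |>
    dplyr::count(.data$classification, name = "n") |>
    tidyr::complete(
      classification = c("on_pathway", "off_pathway", "not_significant",
                         "reference_degenerate"),
      fill = list(n = 0L)
    )
  summary <- tibble(
    n_matched = nrow(rows),
    n_unmatched = n_unmatched,
    n_on_pathway = counts$n[counts$classification == "on_pathway"],
    n_off_pathway = counts$n[counts$classification == "off_pathway"],
    n_not_significant = counts$n[counts$classification == "not_significant"],
    n_reference_degenerate = counts$n[counts$classification == "reference_degenerate"],
    rmsd_global = rmsd_global,
    mean_delta_n = if (any(use)) mean(rows$delta_n[use]) else NA_real_,
    mean_cos_theta = if (any(use)) mean(rows$cos_theta[use]) else NA_real_
  )
  structure(
    list(
      test_state = attr(test, "state_name") %||% "test",
      reference_open = attr(open_ref, "state_name") %||% "open",
      reference_closed = attr(closed_ref, "state_name") %||% "closed",
      rows = rows,
      rmsd_global = rmsd_global,
      rmsd_by_subdomain = rmsd_by_subdomain,
      counts = counts,
      summary = summary,
      threshold = threshold,
      cos_cutoff = cos_cutoff
    ),
    class = "state_comparison"
  )
}

#' @exportS3Method base::print
print.state_comparison <- function(x, ...) {
  cat("State comparison:", x$test_state, "vs open =", x$reference_open,
      "/ closed =", x$reference_closed, "\n")
  cat(sprintf(
    "  %d matched peaks: %d on-pathway, %d off-pathway, %d not significant, %d degenerate\n",
    x$summary$n_matched, x$summary$n_on_pathway, x$summary$n_off_pathway,
    x$summary$n_not_significant, x$summary$n_reference_degenerate))
  cat(sprintf("  RMSD_1.0 global: %.3f  mean delta_n: %.3f  mean cos theta: %.3f\n",
              x$rmsd_global, x$summary$mean_delta_n, x$summary$mean_cos_theta))
  invisible(x)
}
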