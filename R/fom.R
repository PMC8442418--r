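# Beam-path figure of merit and ranking. Omega = Ip * It / (l * Delta q)
# rewards a tall, intense, sharp scattering peak per unit dose (dose taken
# proportional to the attenuation path length l).

#' Figure of merit of a beam path
#'
#' Omega = `I_p * I_t / (l * delta_q)`: linear in the peak and total relative
#' intensities, inverse in the half-width-at-half-maximum q spread (smeared
#' peaks are harder to distinguish) and in the path length (a proxy for the
#' radiation dose delivered along the beam).
#'
#' @param I_p peak relative intensity.
#' @param I_t total relative intensity (area under the profile), nm^-1.
#' @param delta_q HWHM spread of q, nm^-1 (> 0).
#' @param l attenuation path length, cm (> 0).
#' @return Omega (vectorized over its arguments).
#' @examples
#' figure_of_merit(1, 1, 1, 1)
#' @export
figure_of_merit <- function(I_p, I_t, delta_q, l) {
  if (any(l <= 0)) stop("l must be > 0 (paths without target are flagged upstream)")
  if (any(delta_q <= 0)) stop("delta_q must be > 0")
  if (any(I_p < 0) || any(I_t < 0)) stop("intensities must be >= 0")
  I_p * I_t / (l * delta_q)
}

#' Assemble figure-of-merit records
#'
#' Builds the per-path record [rank_paths()] consumes, computing `omega` from
#' its components when not supplied directly (e.g. when working from a
#' published table that prints Omega alongside its inputs).
#'
#' @param path character label for each path.
#' @param I_p,I_t,delta_q profile summaries (see [summarize_profile()]).
#' @param l attenuation path length, cm (may be `NA` when `omega` is given).
#' @param omega optional precomputed figure of merit.
#' @param orientation,index optional path coordinates used for deterministic
#'   tie-breaking.
#' @param intersects_excluded logical flag: the path crosses a radiosensitive
#'   (excluded) region.
#' @return a data.frame of FOM records.
#' @export
fom_record <- function(path, I_p, I_t, delta_q, l = NA_real_, omega = NULL,
                       orientation = NA_character_, index = NA_integer_,
                       intersects_excluded = FALSE) {
  if (is.null(omega)) omega <- figure_of_merit(I_p, I_t, delta_q, l)
  data.frame(path = path, orientation = orientation, index = index,
             I_p = I_p, I_t = I_t, delta_q = delta_q, l = l,
             omega = omega, intersects_excluded = intersects_excluded)
}

#' Rank beam paths by figure of merit
#'
#' Sorts candidate records by Omega (descending; exact ties broken by
#' orientation then index, ascending) and normalizes each Omega by the
#' maximum over the surviving candidates (`omega_norm = Omega / Omega_max`,
#' so the best path scores 1). Paths flagged `candidate = FALSE` (e.g. no
#' target pixels) and, under the `"drop"` policy, paths intersecting an
#' excluded region are kept in the output with a reason tag but receive no
#' rank and no normalized score.
#'
#' The default exclusion policy `"none"` does not discard radiosensitive
#' intersections automatically; it emits a warning naming them so that they
#' can be reviewed.
#'
#' @param records data.frame with at least an `omega` column; recognized
#'   optional columns: `candidate`, `intersects_excluded`, `orientation`,
#'   `index`.
#' @param exclusion `"none"` (warn about paths crossing excluded regions) or
#'   `"drop"` (remove them from the candidate set).
#' @return the records with added columns `candidate`, `excluded_reason`,
#'   `omega_norm` and `rank`, ordered ranked candidates first.
#' @export
rank_paths <- function(records, exclusion = c("none", "drop")) {
  exclusion <- match.arg(exclusion)
  stopifnot(is.data.frame(records), "omega" %in% names(records))
  n <- nrow(records)
  if (!n) stop("no records to rank")
  if (is.null(records$candidate)) records$candidate <- TRUE
  if (is.null(records$intersects_excluded)) records$intersects_excluded <- FALSE
  if (is.null(records$orientation)) records$orientation <- NA_character_
  if (is.null(records$index)) records$index <- NA_integer_

  records$excluded_reason <- ifelse(records$candidate, "", "no target on path")
  hits <- which(records$intersects_excluded & records$candidate)
  if (length(hits)) {
    labels <- paste0(records$orientation[hits], " ", records$index[hits],
                     collapse = ", ")
    if (exclusion == "drop") {
      records$candidate[hits] <- FALSE
      records$excluded_reason[hits] <- "intersects excluded region"
    } else {
      warning(sprintf("path(s) intersect excluded (radiosensitive) regions: %s",
                      labels), call. = FALSE)
    }
  }

  cand <- which(records$candidate)
  if (!length(cand)) stop("all paths excluded; nothing to rank")
  omega_max <- max(records$omega[cand])
  records$omega_norm <- NA_real_
  records$omega_norm[cand] <- records$omega[cand] / omega_max

  ord <- cand[order(-records$omega[cand],
                    records$orientation[cand],
                    records$index[cand])]
  records$rank <- NA_integer_
  records$rank[ord] <- seq_along(ord)
  records[c(ord, setdiff(seq_len(n), ord)), , drop = FALSE]
}

#' Score and rank every path of a mask scan
#'
#' End-to-end composition: measure each Cartesian path through the mask
#' ([scan_paths()]), run the forward model on each path that crosses the
#' target ([model_profile()]), summarize the smeared profile, compute Omega,
#' and rank. Paths with no target pixels get `omega = 0` and
#' `candidate = FALSE` so whole-mask scans complete. The target-to-detector
#' distance is taken constant across the scan (single `beam`).
#'
#' @param mask a [labeled_mask()].
#' @param medium a [medium_properties()].
#' @param beam a [beam_geometry()] (its `L0` and wavelength apply to every
#'   path).
#' @param q_center central scattering vector of the target material, nm^-1.
#' @param orientations,stride,include_target_in_path see [scan_paths()].
#' @param exclusion see [rank_paths()].
#' @param n_q,kernel_width_factor see [model_profile()].
#' @return a ranked data.frame: path measurements joined with `I_p`, `I_t`,
#'   `delta_q`, `omega`, `omega_norm`, `candidate`, `rank`.
#' @export
evaluate_mask_scan <- function(mask, medium, beam, q_center = 13.4,
                               orientations = c("row", "column"), stride = 1L,
                               exclusion = c("none", "drop"),
                               include_target_in_path = TRUE,
                               n_q = 2048, kernel_width_factor = 0.35) {
  exclusion <- match.arg(exclusion)
  paths <- scan_paths(mask, orientations, stride, include_target_in_path)
  n <- nrow(paths)
  paths$I_p <- 0; paths$I_t <- 0; paths$delta_q <- NA_real_
  paths$omega <- 0
  paths$candidate <- paths$target_pixels > 0L
  for (i in seq_len(n)) {
    if (!paths$candidate[i]) next
    res <- tryCatch(
      model_profile(medium, paths$r_t_eff[i], paths$l[i], beam, q_center,
                    n_q = n_q, kernel_width_factor = kernel_width_factor),
      error = function(e) {
        stop(sprintf("path %s %d: %s", paths$orientation[i], paths$index[i],
                     conditionMessage(e)), call. = FALSE)
      })
    s <- res$summary
    paths$I_p[i] <- s$I_p
    paths$I_t[i] <- s$I_t
    paths$delta_q[i] <- s$delta_q
    paths$omega[i] <- figure_of_merit(s$I_p, s$I_t, s$delta_q, paths$l[i])
  }
  paths$path <- paste(paths$orientation, paths$index)
  rank_paths(paths, exclusion = exclusion)
}

#' Write a ranked figure-of-merit table to TSV
#'
#' Fixed 9-significant-digit scientific notation for numeric columns so runs
#' are byte-stable.
#'
#' @param records ranked records from [rank_paths()] or
#'   [evaluate_mask_scan()].
#' @param path output file path.
#' @param top optional: keep only the `top` ranked candidates.
#' @export
write_fom_table <- function(records, path, top = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(top)) {
    records <- records[!is.na(records$rank) & records$rank <= top, , drop = FALSE]
  }
  out <- records
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.8e", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference per-path scattering summaries for lobe targets
#'
#' Published per-path summaries (peak relative intensity, total relative
#' intensity, HWHM q spread, figure of merit and its normalized value) for a
#' selection of horizontal and vertical pencil-beam paths through temporal
#' and frontal lobe target regions segmented from a 2D scout image of a human
#' head. Useful as worked input for [rank_paths()] and as a consistency
#' reference; the absolute values depend on the original segmentation and are
#' not regenerable from this package alone.
#'
#' @return a data.frame with columns `region`, `path`, `orientation`,
#'   `index`, `I_p`, `I_t`, `delta_q`, `omega`, `omega_norm_reported`.
#' @export
reference_path_summaries <- function() {
  path <- system.file("extdata", "lobe_path_summaries.tsv",
                      package = "saxsbeam", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
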