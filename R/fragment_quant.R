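## Capillary-electrophoresis fragment quantification: ladder-based sizing,
## peak-to-amplicon assignment, and reference-gene normalization.

#' Size target peaks against a ladder
#'
#' Converts peak migration (scan units) to fragment size (bp) using the
#' in-lane size standard. `piecewise_linear` interpolates between flanking
#' ladder points; `local_southern` fits the classic reciprocal mobility
#' model `L = c + k / (m - m0)` to the two overlapping triplets of ladder
#' points flanking the target and averages the two estimates. Targets
#' outside the ladder span are sized by extending the terminal fit and
#' flagged as extrapolated.
#'
#' @param ladder_migration,ladder_bp migrations and known sizes of the
#'   ladder peaks (equal length, >= 2; both strictly increasing).
#' @param target_migration migrations to size.
#' @param method `"piecewise_linear"` (default) or `"local_southern"`.
#' @return data.frame with `migration`, `size_bp`, `extrapolated`.
#' @export
size_peaks <- function(ladder_migration, ladder_bp, target_migration,
                       method = c("piecewise_linear", "local_southern")) {
  method <- match.arg(method)
  n <- length(ladder_migration)
  if (n < 2L || length(ladder_bp) != n)
    stop("calibration error: need >= 2 ladder peaks with matching sizes")
  if (any(diff(ladder_migration) <= 0) || any(diff(ladder_bp) <= 0))
    stop("calibration error: ladder must be strictly increasing in migration and size")
  extrapolated <- target_migration < ladder_migration[1L] |
    target_migration > ladder_migration[n]
  size_bp <- if (method == "piecewise_linear") {
    interp_linear(ladder_migration, ladder_bp, target_migration)
  } else {
    vapply(target_migration, local_southern_size,
           numeric(1), m = ladder_migration, L = ladder_bp)
  }
  data.frame(migration = target_migration, size_bp = size_bp,
             extrapolated = extrapolated)
}

## Piecewise-linear interpolation with linear (not constant) extrapolation
## from the terminal segments.
interp_linear <- function(x, y, xout) {
  n <- length(x)
  out <- stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  lo <- xout < x[1L]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    out[lo] <- y[1L] + s * (xout[lo] - x[1L])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

## Fit L = c + k/(m - m0) through three ladder points; closed form via the
## ratio of size differences. Falls back to linear interpolation when the
## triplet is exactly collinear (m0 at infinity).
southern_triplet <- function(m, L, target) {
  r <- ((L[1] - L[2]) / (L[2] - L[3])) * ((m[3] - m[2]) / (m[2] - m[1]))
  if (!is.finite(r) || abs(r - 1) < 1e-12)
    return(interp_linear(m, L, target))
  m0 <- (m[3] - r * m[1]) / (1 - r)
  k <- (L[1] - L[2]) * (m[1] - m0) * (m[2] - m0) / (m[2] - m[1])
  c0 <- L[1] - k / (m[1] - m0)
  c0 + k / (target - m0)
}

local_southern_size <- function(target, m, L) {
  n <- length(m)
  if (n < 3L) return(interp_linear(m, L, target))
  i <- findInterval(target, m, all.inside = TRUE)  # segment [i, i+1]
  ests <- c(if (i >= 2L) southern_triplet(m[(i - 1L):(i + 1L)],
                                          L[(i - 1L):(i + 1L)], target),
            if (i + 2L <= n) southern_triplet(m[i:(i + 2L)],
                                              L[i:(i + 2L)], target))
  mean(ests)
}

#' Assign sized peaks to a panel of expected amplicons
#'
#' Each peak is assigned to the nearest expected amplicon size within
#' `tol`; peaks matching nothing are reported separately. The output has
#' one record per defined isoform per sample; isoforms with no matching
#' peak get `raw_area = 0` and a below-detection flag. Panels whose
#' expected sizes are closer than `2 * tol` are rejected as ambiguous.
#'
#' @param peaks data.frame with `sample_id`, `size_bp`, `area`.
#' @param panel data.frame with `gene_id`, `isoform_id`, `expected_size`
#'   (unique per gene/isoform).
#' @param tol assignment tolerance in bp (default 2).
#' @return data.frame with `sample_id`, `gene_id`, `isoform_id`,
#'   `raw_area`, `below_detection`; unassigned peaks are kept in the
#'   `"unassigned"` attribute.
#' @export
assign_isoforms <- function(peaks, panel, tol = 2) {
  stopifnot(all(c("sample_id", "size_bp", "area") %in% names(peaks)),
            all(c("gene_id", "isoform_id", "expected_size") %in% names(panel)))
  if (anyDuplicated(panel[, c("gene_id", "isoform_id")]))
    stop("ambiguous panel: duplicate (gene, isoform) definitions")
  sizes <- sort(panel$expected_size)
  if (length(sizes) > 1L && any(diff(sizes) < 2 * tol))
    stop("ambiguous panel: expected sizes closer than 2*tol (", 2 * tol,
         " bp)")
  if (any(peaks$area < 0)) stop("negative peak area")
  nearest <- vapply(peaks$size_bp, function(s) {
    d <- abs(panel$expected_size - s)
    j <- which.min(d)
    if (d[j] <= tol) j else NA_integer_
  }, integer(1))
  samples <- unique(peaks$sample_id)
  grid <- expand.grid(sample_id = samples,
                      def = seq_len(nrow(panel)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(peaks$sample_id, nearest)
  agg <- tapply(peaks$area, key, sum)
  raw <- agg[paste(grid$sample_id, grid$def)]
  raw[is.na(raw)] <- 0
  out <- data.frame(sample_id = grid$sample_id,
                    gene_id = panel$gene_id[grid$def],
                    isoform_id = panel$isoform_id[grid$def],
                    raw_area = as.numeric(raw),
                    below_detection = as.numeric(raw) == 0,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$gene_id, out$isoform_id), ]
  rownames(out) <- NULL
  attr(out, "unassigned") <- peaks[is.na(nearest), , drop = FALSE]
  out
}

#' Normalize raw areas by the reference genes
#'
#' Divides each sample's target areas by the geometric mean of that
#' sample's reference-gene areas, making abundances comparable across
#' lanes and runs. Samples in which every reference is undetected are
#' dropped and reported.
#'
#' @param records output of [assign_isoforms()] (or any data.frame with
#'   `sample_id`, `gene_id`, `isoform_id`, `raw_area`, `below_detection`).
#' @param reference_gene_ids character vector of reference gene labels.
#' @return data.frame of the non-reference records with an added
#'   `norm_abundance` column; samples dropped for lacking reference signal
#'   are listed in the `"dropped_samples"` attribute.
#' @export
normalize_abundances <- function(records, reference_gene_ids) {
  is_ref <- records$gene_id %in% reference_gene_ids
  if (!any(is_ref))
    stop("no reference-gene records found for: ",
         paste(reference_gene_ids, collapse = ", "))
  refs <- records[is_ref, , drop = FALSE]
  geo <- tapply(refs$raw_area, refs$sample_id, function(a) {
    a <- a[a > 0]
    if (length(a) == 0L) NA_real_ else exp(mean(log(a)))
  })
  dropped <- names(geo)[is.na(geo)]
  out <- records[!is_ref, , drop = FALSE]
  out$norm_abundance <- out$raw_area / as.numeric(geo[out$sample_id])
  out <- out[!out$sample_id %in% dropped, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_samples") <- dropped
  out
}

#' Call peaks on a raw fluorescence trace
#'
#' Simple peak caller for simulated electropherograms: the trace is
#' smoothed with a centred moving average, local maxima above a fraction of
#' the trace maximum are kept, and each peak's area is the trapezoidal
#' integral between its flanking local minima.
#'
#' @param migration,signal numeric vectors (equal length, migration
#'   strictly increasing).
#' @param min_frac minimum peak height as a fraction of the smoothed trace
#'   maximum (default 0.05).
#' @param window moving-average window in points (odd; default 5).
#' @return data.frame with `migration` (apex), `height`, `area`.
#' @export
call_peaks <- function(migration, signal, min_frac = 0.05, window = 5L) {
  stopifnot(length(migration) == length(signal),
            all(diff(migration) > 0), window >= 1L)
  if (window %% 2L == 0L) window <- window + 1L
  k <- rep(1 / window, window)
  sm <- stats::filter(signal, k, sides = 2)
  sm[is.na(sm)] <- signal[is.na(sm)]
  sm <- as.numeric(sm)
  n <- length(sm)
  thr <- min_frac * max(sm)
  idx <- 2L:(n - 1L)
  apex <- idx[sm[idx] > sm[idx - 1L] & sm[idx] >= sm[idx + 1L]]
  apex <- apex[sm[apex] >= thr]
  if (length(apex) == 0L)
    return(data.frame(migration = numeric(0), height = numeric(0),
                      area = numeric(0)))
  ## flanking minima: lowest point between consecutive apexes / trace ends
  bounds <- vapply(seq_along(apex), function(j) {
    lo <- if (j == 1L) 1L else apex[j - 1L] +
      which.min(sm[apex[j - 1L]:apex[j]]) - 1L
    hi <- if (j == length(apex)) n else apex[j] +
      which.min(sm[apex[j]:apex[j + 1L]]) - 1L
    c(lo, hi)
  }, integer(2))
  area <- vapply(seq_along(apex), function(j) {
    i <- bounds[1L, j]:bounds[2L, j]
    sum(diff(migration[i]) * (sm[i][-1L] + sm[i][-length(i)]) / 2)
  }, numeric(1))
  data.frame(migration = migration[apex], height = sm[apex], area = area)
}

#' Read a peak-table CSV
#'
#' Reads fragment-analysis software exports with a configurable column
#' mapping (defaults match this package's own writers).
#'
#' @param path CSV file.
#' @param columns named character vector mapping canonical names
#'   (`sample_id`, `dye`, `migration`, `height`, `area`) to the file's
#'   column names.
#' @return data.frame with canonical column names.
#' @export
read_peak_table <- function(path,
                            columns = c(sample_id = "sample_id",
                                        dye = "dye",
                                        migration = "migration",
                                        height = "height",
                                        area = "area")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing) > 0L)
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  out <- raw[, unname(columns), drop = FALSE]
  names(out) <- names(columns)
  out
}

#' Read / write an amplicon panel
#'
#' The panel maps each (gene, isoform) to its expected amplicon size in bp.
#' Stored as YAML: a list of records with `gene_id`, `isoform_id`,
#' `expected_size`.
#'
#' @param path YAML file.
#' @return data.frame with `gene_id`, `isoform_id`, `expected_size`.
#' @export
read_panel <- function(path) {
  recs <- yaml::read_yaml(path)
  do.call(rbind, lapply(recs, function(r)
    data.frame(gene_id = r$gene_id, isoform_id = r$isoform_id,
               expected_size = as.numeric(r$expected_size),
               stringsAsFactors = FALSE)))
}

#' @rdname read_panel
#' @param panel data.frame with `gene_id`, `isoform_id`, `expected_size`.
#' @export
write_panel <- function(panel, path) {
  recs <- lapply(seq_len(nrow(panel)), function(i)
    list(gene_id = panel$gene_id[i], isoform_id = panel$isoform_id[i],
         expected_size = panel$expected_size[i]))
  yaml::write_yaml(recs, path)
  invisible(path)
}
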