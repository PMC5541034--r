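#' FTIR spectrum set
#'
#' Container for absorbance spectra on a shared wavenumber grid
#' (conventionally 4000 -> 600 cm-1, descending). Processing provenance only
#' moves forward: raw -> averaged -> derivative -> normalized.
#'
#' @param wavenumber strictly monotone grid (cm-1).
#' @param values matrix, one column per spectrum, rows matching the grid.
#' @param samples column ids.
#' @param fraction sample fraction tag (plant residue, microbial pellet, ...).
#' @param provenance processing state.
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumber, values, samples,
                         fraction = "residue", provenance = "raw") {
  values <- as.matrix(values)
  if (length(wavenumber) != nrow(values))
    stopf("grid length does not match spectra rows")
  dw <- diff(wavenumber)
  if (!(all(dw > 0) || all(dw < 0))) stopf("wavenumber grid must be strictly monotone")
  if (any(!is.finite(values))) stopf("non-finite absorbance values")
  colnames(values) <- samples
  structure(list(wavenumber = as.numeric(wavenumber), values = values,
                 samples = as.character(samples), fraction = fraction,
                 provenance = provenance),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d spectra x %d points (%g-%g cm-1), %s/%s\n",
              ncol(x$values), nrow(x$values), max(x$wavenumber),
              min(x$wavenumber), x$fraction, x$provenance))
  invisible(x)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of the spectra within each group.
#'
#' @param spectra a `spectrum_set`.
#' @param groups grouping vector, one entry per spectrum (default: a single
#'   group, i.e. the grand mean).
#' @return `spectrum_set` with one spectrum per group, provenance "averaged".
#' @export
average_replicates <- function(spectra, groups = rep("all", ncol(spectra$values))) {
  if (length(groups) != ncol(spectra$values))
    stopf("groups must have one entry per spectrum")
  g <- base::factor(groups, levels = unique(groups))
  m <- sapply(levels(g), function(l)
    rowMeans(spectra$values[, g == l, drop = FALSE]))
  spectrum_set(spectra$wavenumber, m, levels(g), spectra$fraction, "averaged")
}

# Savitzky-Golay coefficient matrix: row d+1 gives the d-th derivative
# coefficients (in index units) for a centered window of half-width h.
savgol_coefs <- function(window, polyorder) {
  h <- (window - 1) / 2
  A <- outer(-h:h, 0:polyorder, `^`)
  solve(crossprod(A), t(A))    # (polyorder+1) x window
}

#' First Savitzky-Golay derivative
#'
#' Local least-squares polynomial smoothing derivative (default 13-point
#' window, order-2 polynomial). Edges are handled by evaluating the
#' polynomial fitted to the first/last full window at the edge positions
#' (polynomial extrapolation of the fit). The derivative is scaled by the
#' grid spacing to physical units (absorbance per cm-1), so a ramp of slope
#' c per cm-1 gives a constant derivative c regardless of grid direction.
#'
#' @param spectra a `spectrum_set` on a uniform grid (relative tolerance
#'   1e-6 on the spacing).
#' @param window odd window length > `polyorder` and < the series length.
#' @param polyorder fitted polynomial degree (default 2).
#' @return `spectrum_set`, provenance "derivative".
#' @export
savgol_first_derivative <- function(spectra, window = 13, polyorder = 2) {
  if (window %% 2 != 1) stopf("window must be odd")
  if (window <= polyorder) stopf("window must exceed polyorder")
  np <- nrow(spectra$values)
  if (window >= np) stopf("window (%d) >= series length (%d)", window, np)
  dw <- diff(spectra$wavenumber)
  if (max(abs(dw - mean(dw))) > 1e-6 * abs(mean(dw)))
    stopf("wavenumber grid not uniform")
  step <- mean(dw)                       # signed (negative for 4000 -> 600)
  h <- (window - 1) / 2
  C <- savgol_coefs(window, polyorder)   # rows: value, 1st deriv (index units), ...
  d1 <- C[2, ]

  vals <- spectra$values
  out <- matrix(0, np, ncol(vals))
  # interior: convolution with the centered first-derivative kernel
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    for (i in (h + 1):(np - h))
      out[i, j] <- sum(d1 * v[(i - h):(i + h)])
    # edges: fit one polynomial to the first/last window, evaluate its
    # derivative at the off-center positions
    bfit <- C %*% v[1:window]            # poly coefficients at window center
    efit <- C %*% v[(np - window + 1):np]
    for (i in 1:h) {
      x <- i - (h + 1)                   # offset from first-window center
      out[i, j] <- poly_deriv_at(bfit, x)
      x2 <- (np - h + i) - (np - h)      # offset i from last-window center
      out[np - h + i, j] <- poly_deriv_at(efit, x2)
    }
  }
  out <- out / step
  spectrum_set(spectra$wavenumber, out, spectra$samples, spectra$fraction,
               "derivative")
}

# derivative of sum_k c[k+1] x^k at x
poly_deriv_at <- function(coefs, x) {
  k <- seq_along(coefs) - 1
  sum(coefs[-1] * k[-1] * x^(k[-1] - 1))
}

#' Standardize spectra
#'
#' Per-spectrum autoscaling to mean 0 and standard deviation 1. The
#' instrument-software convention of reporting "mean = 1" is available as
#' `offset = 1` (a pure translation; distance-based statistics downstream are
#' unaffected). The choice is recorded in the provenance tag.
#'
#' @param spectra a `spectrum_set` (derivative provenance expected).
#' @param offset constant added after standardization (default 0).
#' @return `spectrum_set`, provenance "normalized(offset=...)".
#' @export
normalize_spectra <- function(spectra, offset = 0) {
  v <- spectra$values
  sds <- apply(v, 2, stats::sd)
  if (any(sds < 1e-300))
    stopf("zero-variance spectrum: %s",
          paste(spectra$samples[sds < 1e-300], collapse = ", "))
  out <- scale(v)[, , drop = FALSE] + offset
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  spectrum_set(spectra$wavenumber, out, spectra$samples, spectra$fraction,
               sprintf("normalized(offset=%g)", offset))
}

#' PERMANOVA on processed spectra
#'
#' Euclidean distances between processed spectra are fed to [permanova()]
#' with the factorial design (derivative spectra take negative values, so the
#' Euclidean metric is used rather than Bray-Curtis).
#'
#' @param spectra a processed `spectrum_set`.
#' @param metadata sample metadata covering the spectra.
#' @param terms design terms, as in [permanova()].
#' @param ... passed to [permanova()].
#' @return a `permanova_result`.
#' @export
spectra_permanova <- function(spectra, metadata, terms, ...) {
  X <- t(spectra$values)
  d <- as.matrix(stats::dist(X))
  permanova(dist_matrix(d, metric = "euclidean"), metadata, terms, ...)
}

#' Read / write spectra CSV
#'
#' Interchange format: CSV with a `wavenumber` first column and one column
#' per sample; `#` lines are metadata.
#' @param path file path.
#' @param fraction,provenance tags attached on read.
#' @return a `spectrum_set`.
#' @export
read_spectra <- function(path, fraction = "residue", provenance = "raw") {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  spectrum_set(df[[1]], as.matrix(df[, -1, drop = FALSE]),
               colnames(df)[-1], fraction, provenance)
}

#' @param spectra a `spectrum_set`.
#' @param header optional `#` metadata lines.
#' @rdname read_spectra
#' @export
write_spectra <- function(spectra, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(wavenumber = spectra$wavenumber, spectra$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
}
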