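#' Correspondence analysis of a contingency table
#'
#' Classical (chi-square) correspondence analysis: the matrix of
#' standardized residuals `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` (with `P`
#' the table of proportions, `r`/`c` the row and column masses) is
#' factorized by SVD, and rows and columns are reported in principal
#' coordinates. Per-axis inertias are the squared singular values; the total
#' inertia equals the Pearson chi-square statistic of the table divided by
#' its grand total.
#'
#' @param x Nonnegative numeric matrix (e.g. species x nucleotide-by-codon-
#'   position counts) with no all-zero row or column.
#' @return Object of class `ca_fit`: list with `row_coords`, `col_coords`
#'   (principal coordinates, axes in columns), `sv` (singular values),
#'   `inertia` (per axis), `inertia_prop`, `total_inertia`, `row_mass`,
#'   `col_mass`, and `residuals` (the standardized residual matrix).
#' @examples
#' fit <- correspondence_analysis(matrix(c(10, 0, 0, 10), 2))
#' fit$total_inertia  # 1
#' @export
correspondence_analysis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be nonnegative")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("all-zero row or column in the table")
  n <- sum(x)
  if (n == 0) stop("empty table")
  P <- x / n
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r), nrow = length(r)) %*%
    (P - tcrossprod(r, cm)) %*% diag(1 / sqrt(cm), nrow = length(cm))
  dimnames(S) <- dimnames(x)
  dec <- svd(S)
  keep <- which(dec$d > max(dec$d[1L], 1) * 1e-12)
  if (!length(keep)) stop("rank-0 table: no variation to decompose")
  d <- dec$d[keep]
  axes <- paste0("Axis", seq_along(keep))
  row_coords <- sweep(dec$u[, keep, drop = FALSE], 1L, sqrt(r), "/") %*% diag(d, length(d))
  col_coords <- sweep(dec$v[, keep, drop = FALSE], 1L, sqrt(cm), "/") %*% diag(d, length(d))
  dimnames(row_coords) <- list(rownames(x), axes)
  dimnames(col_coords) <- list(colnames(x), axes)
  structure(
    list(row_coords = row_coords, col_coords = col_coords,
         sv = d, inertia = d^2, inertia_prop = d^2 / sum(d^2),
         total_inertia = sum(dec$d^2),
         row_mass = r, col_mass = cm, residuals = S),
    class = "ca_fit"
  )
}

#' @export
print.ca_fit <- function(x, ...) {
  cat(sprintf("<correspondence analysis> %d x %d table, total inertia %.4f\n",
              nrow(x$row_coords), nrow(x$col_coords), x$total_inertia))
  cat("axis inertia fractions:",
      paste(sprintf("%.3f", x$inertia_prop), collapse = " "), "\n")
  invisible(x)
}

#' Species-by-category composition table for correspondence analysis
#'
#' Builds the nucleotide x codon-position count table (categories `A1, C1,
#' G1, T1, A2, ... T3`) for a set of species, each represented by its
#' H-strand CDS collection, ready for [correspondence_analysis()].
#'
#' @param cds_sets Named list; each element a character vector of in-frame
#'   coding sequences for one species.
#' @param code Genetic code (stop-codon recognition).
#' @return Integer matrix, species in rows, 12 categories in columns.
#' @export
composition_ca_table <- function(cds_sets, code = genetic_code()) {
  rows <- lapply(cds_sets, function(set) {
    prof <- codon_position_profile(set, code = code)
    cnt <- prof$counts
    stats::setNames(as.integer(t(cnt)),
                    paste0(rep(colnames(cnt), 3), rep(rownames(cnt), each = 4)))
  })
  do.call(rbind, rows)
}
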