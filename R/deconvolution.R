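# Immune cell-fraction deconvolution: bulk expression is modeled as a
# nonnegative combination of cell-type signature profiles, solved by
# constrained least squares (f >= 0, sum(f) <= 1), with the remainder
# reported as an uncharacterized "Other" fraction.

#' Lawson-Hanson nonnegative least squares
#'
#' Active-set solver for `min ||A x - b||^2` subject to `x >= 0`; the
#' constrained-regression primitive behind [deconvolve()].
#'
#' @param A Design matrix.
#' @param b Response vector.
#' @param tol Dual-feasibility tolerance (default `1e-10` scaled by the
#'   problem magnitude).
#' @return List with `x` (solution) and `residual` (2-norm).
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  scale <- max(abs(crossprod(A, b)), 1e-300)
  w <- as.numeric(crossprod(A, b))
  it <- 0L
  max_it <- 30L * n
  while (any(!passive) && any(w[!passive] > tol * scale) && it < max_it) {
    it <- it + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) break
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sqrt(sum((b - A %*% x)^2)))
}

#' Deconvolve immune cell fractions from bulk expression
#'
#' Solves `min || S f - m ||^2` subject to `f >= 0` and `sum(f) <= 1`,
#' where `S` is the gene x cell-type signature matrix and `m` the bulk
#' mixture.  The inequality is handled exactly by adding a nonnegative
#' slack component and a heavily weighted row enforcing
#' `sum(f) + slack = 1`; whatever the cell types do not explain is
#' returned as the `Other` fraction.  Genes in the signature but absent
#' from the mixture are imputed 0 with a warning.
#'
#' @param mixture Named numeric vector (gene to expression) or a data
#'   frame with columns `gene` and an expression column.
#' @param signature Numeric matrix with gene rownames and cell-type
#'   colnames, or a data frame whose first column is `gene`.
#' @param sum_to_one Force `sum(f) = 1` (no `Other` remainder).
#' @param normalize Rescale the mixture and every signature column to a
#'   common total before solving (off by default: the solver works in
#'   the units supplied, preserving the absolute-fraction reading when
#'   mixture and signature share a scale).
#' @param tol Solver tolerance.
#' @return Named numeric vector of class `cell_fractions` (cell types
#'   plus `Other`), summing to 1.
#' @export
deconvolve <- function(mixture, signature, sum_to_one = FALSE,
                       normalize = FALSE, tol = 1e-10) {
  S <- as_signature_matrix(signature)
  m <- as_mixture_vector(mixture)
  missing_genes <- setdiff(rownames(S), names(m))
  if (length(missing_genes) > 0) {
    warning(sprintf("%d signature gene(s) absent from mixture, imputed 0",
                    length(missing_genes)), call. = FALSE)
    m[missing_genes] <- 0
  }
  m <- m[rownames(S)]
  if (any(colSums(abs(S)) == 0))
    stop_config("signature has an all-zero cell-type column")
  if (qr(S)$rank < ncol(S))
    warning("signature matrix is rank deficient; fractions may not be uniquely determined",
            call. = FALSE)
  if (normalize) {
    tot <- sum(m)
    if (tot > 0) m <- m / tot * 1e6
    S <- sweep(S, 2, pmax(colSums(S), 1e-300), "/") * 1e6
  }
  k <- ncol(S)
  # Phase 1: plain nonnegative least squares.  When the fractions already
  # satisfy sum(f) <= 1 the inequality is inactive and this solution is
  # exact.  Otherwise the bound is active: re-solve with the equality
  # sum(f) = 1 enforced through a weighted row (weight moderate, so the
  # data rows keep numerical influence) and project onto the simplex.
  fit <- nnls_solve(S, m, tol = tol)
  f <- fit$x
  if (sum_to_one || sum(f) > 1) {
    w <- 1e3 * max(max(abs(S)), max(abs(m)), 1e-12)
    A <- rbind(S, rep(w, k))
    fit <- nnls_solve(A, c(m, w), tol = tol)
    f <- fit$x
    fit$residual <- sqrt(sum((m - S %*% f)^2))
  }
  f[f < 0] <- 0
  if (sum(f) > 1) f <- f / sum(f)
  out <- c(stats::setNames(f, colnames(S)), Other = max(0, 1 - sum(f)))
  structure(out, class = "cell_fractions", residual = fit$residual)
}

as_signature_matrix <- function(signature) {
  if (is.data.frame(signature)) {
    gene_col <- if ("gene" %in% names(signature)) "gene" else
      names(signature)[1]
    genes <- as.character(signature[[gene_col]])
    S <- as.matrix(signature[setdiff(names(signature), gene_col)])
    rownames(S) <- genes
  } else {
    S <- as.matrix(signature)
  }
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop_config("signature needs gene rownames and cell-type colnames")
  if (any(S < 0)) stop_config("signature profiles must be nonnegative")
  storage.mode(S) <- "double"
  S
}

as_mixture_vector <- function(mixture) {
  if (is.data.frame(mixture)) {
    gene_col <- if ("gene" %in% names(mixture)) "gene" else
      names(mixture)[1]
    val_col <- setdiff(names(mixture), gene_col)[1]
    mixture <- stats::setNames(as.numeric(mixture[[val_col]]),
                               as.character(mixture[[gene_col]]))
  }
  if (is.null(names(mixture)))
    stop_config("mixture must be named by gene")
  mixture
}

#' @export
print.cell_fractions <- function(x, digits = 4, ...) {
  cat("Deconvolved cell fractions (constrained least squares)\n")
  v <- unclass(x)
  for (nm in names(v)) cat(sprintf("  %-16s %.*f\n", nm, digits, v[[nm]]))
  cat(sprintf("  residual %.4g\n", attr(x, "residual") %||% NA))
  invisible(x)
}

#' CD8+ T-cell fraction covariate
#'
#' @param fractions A `cell_fractions` vector (needed for
#'   `source = "deconvolution"`).
#' @param source `"deconvolution"` (CD8+ T-cell component of
#'   `fractions`) or `"external_estimate"` (pass-through of an estimate
#'   produced by an orthogonal method, e.g. V(D)J-recombination copy
#'   number).
#' @param external Externally supplied estimate, required for
#'   `source = "external_estimate"`.
#' @param cell_type Name of the CD8 component, default `"T.cells.CD8"`.
#' @return A single fraction.
#' @export
t_cell_fraction <- function(fractions = NULL,
                            source = c("deconvolution",
                                       "external_estimate"),
                            external = NULL,
                            cell_type = "T.cells.CD8") {
  source <- match.arg(source)
  if (source == "external_estimate") {
    if (is.null(external) || is.na(external))
      stop_config("external_estimate requested but no estimate supplied")
    return(as.numeric(external))
  }
  if (is.null(fractions) || !cell_type %in% names(fractions))
    stop_config("fractions must contain a %s component", cell_type)
  as.numeric(fractions[[cell_type]])
}

#' Synthetic marker-block signature matrix
#'
#' Builds a small signature with a few high-expression marker genes per
#' cell type over a low nonspecific baseline; used for tests, examples
#' and the shipped text fixture.  Synthetic: the profiles are not
#' derived from any published signature.
#'
#' @param n_genes Total genes (>= 2 per cell type).
#' @param cell_types Cell-type names.
#' @param markers_per_type Marker genes per cell type.
#' @param seed Seed for the profile draw.
#' @return Numeric matrix, genes x cell types.
#' @export
synthetic_signature <- function(n_genes = 50, cell_types = CELL_TYPES,
                                markers_per_type = 4, seed = 42L) {
  k <- length(cell_types)
  if (n_genes < k * markers_per_type)
    stop_config("need at least %d genes", k * markers_per_type)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  S <- matrix(stats::runif(n_genes * k, 0.1, 2), nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              cell_types))
  for (j in seq_len(k)) {
    rows <- ((j - 1) * markers_per_type + 1):(j * markers_per_type)
    S[rows, j] <- stats::runif(markers_per_type, 40, 120)
  }
  S
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
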