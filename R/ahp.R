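#' Pairwise comparison matrix for AHP weighting
#'
#' Holds the Saaty-scale judgments comparing the importance of each
#' criterion against every other: `a[i, j]` is the importance of criterion
#' `i` over criterion `j` (1 = equal, 3 = moderate, 5 = strong, 7 = very
#' strong, with reciprocals for the reverse comparisons). Entries must be
#' positive and the diagonal 1; reciprocity (`a[i,j] * a[j,i] == 1`) is
#' checked but deviations only warn, so a matrix can be analysed exactly as
#' published even when one of its pairs is inconsistent.
#'
#' @param a square numeric matrix of positive judgments.
#' @param labels criterion names (defaults to rownames or C1..Cn).
#' @return A `pairwise_matrix` object.
#' @export
pairwise_matrix <- function(a, labels = NULL) {
  a <- as.matrix(a)
  n <- nrow(a)
  if (n < 2 || ncol(a) != n) stop_invalid("`a` must be a square matrix with n >= 2")
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop_invalid("all pairwise judgments must be finite and positive")
  }
  labels <- labels %||% rownames(a) %||% paste0("C", seq_len(n))
  dimnames(a) <- list(labels, labels)
  m <- structure(list(a = a, labels = labels), class = "pairwise_matrix")
  diagnostics <- validate_matrix(m, quiet = TRUE)
  for (msg in diagnostics$message[diagnostics$severity == "warning"]) warn(msg)
  m
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> %d criteria\n", length(x$labels)))
  print(round(x$a, 4))
  invisible(x)
}

#' Diagnose a pairwise comparison matrix
#'
#' Reports positivity violations and off-unit diagonal entries (hard
#' errors when constructing via [pairwise_matrix()]) and reciprocity
#' deviations `|a[i,j] * a[j,i] - 1| > 1e-9` (warnings only: published
#' matrices are analysed as printed).
#'
#' @param m a [pairwise_matrix()] (or bare matrix).
#' @param quiet suppress warnings and just return the table.
#' @return A tibble with columns `check`, `i`, `j`, `severity`, `message`;
#'   zero rows when the matrix is clean.
#' @export
validate_matrix <- function(m, quiet = FALSE) {
  a <- if (inherits(m, "pairwise_matrix")) m$a else as.matrix(m)
  labels <- rownames(a) %||% paste0("C", seq_len(nrow(a)))
  n <- nrow(a)
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop_invalid("all pairwise judgments must be finite and positive")
  }
  rows <- list()
  for (i in seq_len(n)) {
    if (abs(a[i, i] - 1) > 1e-12) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        check = "diagonal", i = i, j = i, severity = "warning",
        message = sprintf("diagonal entry (%s) is %g, expected 1", labels[i], a[i, i])
      )
    }
  }
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (abs(a[i, j] * a[j, i] - 1) > 1e-9) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          check = "reciprocity", i = i, j = j, severity = "warning",
          message = sprintf(
            "non-reciprocal pair (%s, %s): a[i,j]=%g but a[j,i]=%g (product %g)",
            labels[i], labels[j], a[i, j], a[j, i], a[i, j] * a[j, i]
          )
        )
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    check = character(), i = integer(), j = integer(),
    severity = character(), message = character()
  )
  if (!quiet) for (msg in out$message) warn(msg)
  out
}

#' Read a pairwise matrix from CSV
#'
#' Expects a header row and first column of criterion labels; entries may
#' be decimals or fractions written as `"1/5"`.
#'
#' @param path CSV path.
#' @return A [pairwise_matrix()].
#' @export
read_pairwise_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  labels <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  parse1 <- function(s) {
    s <- trimws(s)
    if (grepl("/", s, fixed = TRUE)) {
      parts <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1]])
      parts[1] / parts[2]
    } else {
      as.numeric(s)
    }
  }
  a <- matrix(vapply(cells, parse1, numeric(1)), nrow = nrow(cells))
  pairwise_matrix(a, labels = labels)
}

# Saaty random consistency index by matrix order; RI(1) = RI(2) = 0.
saaty_ri <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  if (n > length(ri)) stop_invalid(sprintf("random index undefined for n = %d (max 10)", n))
  ri[n]
}

#' Criterion weights and consistency ratio from a pairwise matrix
#'
#' Derives the AHP weight vector and consistency diagnostics. The default
#' `column_normalization` method is Saaty's approximate eigenvector:
#' normalize each column of the judgment matrix to sum 1, then average
#' across columns within each row. `power_iteration` computes the
#' principal right eigenvector instead. Both report
#' `lambda_max = mean((a %*% w) / w)` (the consistency-vector mean),
#' `CI = (lambda_max - n) / (n - 1)`, and `CR = CI / RI(n)` with `RI` the
#' Saaty random index (`CR` defined as 0 for n <= 2). `CR <= 0.1` is the
#' conventional threshold for acceptable judgment consistency.
#'
#' @param m a [pairwise_matrix()] or bare positive square matrix.
#' @param method `"column_normalization"` (default) or `"power_iteration"`.
#' @param max_iter,tol power-iteration controls.
#' @return An `ahp_result` with fields `weights` (named, sums to 1),
#'   `lambda_max`, `CI`, `CR`, `method`, plus the diagnostics table of the
#'   input matrix.
#' @examples
#' m <- pairwise_matrix(rbind(c(1, 2), c(1 / 2, 1)))
#' ahp_weights(m)$weights
#' @export
ahp_weights <- function(m, method = c("column_normalization", "power_iteration"),
                        max_iter = 1000, tol = 1e-12) {
  method <- match.arg(method)
  if (!inherits(m, "pairwise_matrix")) {
    m <- suppressWarnings(pairwise_matrix(m))
  }
  a <- m$a
  n <- nrow(a)
  if (method == "column_normalization") {
    w <- rowMeans(sweep(a, 2, colSums(a), "/"))
  } else {
    w <- rep(1 / n, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w_new <- as.vector(a %*% w)
      w_new <- w_new / sum(w_new)
      if (max(abs(w_new - w)) < tol) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged) {
      abort(sprintf("power iteration did not converge in %d iterations (residual %.3g)",
                    max_iter, max(abs(as.vector(a %*% w) / sum(a %*% w) - w))),
            class = "smcair_error_no_convergence")
    }
  }
  w <- w / sum(w)
  names(w) <- m$labels
  lambda_max <- mean(as.vector(a %*% w) / w)
  ci <- if (n > 2) (lambda_max - n) / (n - 1) else 0
  ri <- saaty_ri(n)
  cr <- if (ri > 0) ci / ri else 0
  structure(
    list(weights = w, lambda_max = lambda_max, CI = ci, CR = cr,
         method = method, n = n,
         diagnostics = validate_matrix(m, quiet = TRUE)),
    class = "ahp_result"
  )
}

#' @export
print.ahp_result <- function(x, ...) {
  cat(sprintf("AHP weights (%s)\n", x$method))
  print(round(x$weights, 4))
  cat(sprintf("lambda_max = %.4f, CI = %.4f, CR = %.4f (%.2f displayed)\n",
              x$lambda_max, x$CI, x$CR, round(x$CR, 2)))
  if (nrow(x$diagnostics)) {
    cat(sprintf("%d matrix diagnostic(s); see $diagnostics\n", nrow(x$diagnostics)))
  }
  invisible(x)
}

#' @export
tidy.ahp_result <- function(x, ...) {
  tibble::tibble(criterion = names(x$weights), weight = unname(x$weights))
}

#' @export
glance.ahp_result <- function(x, ...) {
  tibble::tibble(
    n = x$n, lambda_max = x$lambda_max, CI = x$CI, CR = x$CR,
    consistent = x$CR <= 0.1, method = x$method
  )
}
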