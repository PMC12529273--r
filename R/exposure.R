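#' Case-control contingency table over exposure classes
#'
#' Samples the class raster at each residence and cross-tabulates exposure
#' class (rows, ordered low to high) against group (columns case,
#' control). Classes with zero total still appear as zero rows. Residences
#' falling on nodata cells are not silently dropped: they are excluded
#' from the table and reported in the `exclusions` attribute.
#'
#' @param residences residence tibble with `x`, `y`, `group` (and `id`).
#' @param class_raster a class [smc_raster()] (values 1-3).
#' @param exposure name for the exposure variable (used in reports).
#' @return A `contingency_table`: counts matrix with rows `low`,
#'   `moderate`, `high` and columns `case`, `control`; attributes
#'   `exposure` and `exclusions` (tibble of skipped records).
#' @export
build_contingency <- function(residences, class_raster, exposure = "exposure") {
  residences <- tibble::as_tibble(residences)
  levels_cls <- c(low = 1, moderate = 2, high = 3)
  counts <- matrix(0L, 3, 2, dimnames = list(names(levels_cls), c("case", "control")))
  exclusions <- tibble::tibble(id = character(), x = numeric(), y = numeric(),
                               reason = character())
  if (nrow(residences)) {
    sampled <- sample_raster(residences, class_raster)
    drop <- sampled$nodata
    if (any(drop)) {
      exclusions <- tibble::tibble(
        id = as.character(sampled$id[drop] %||% which(drop)),
        x = sampled$x[drop], y = sampled$y[drop],
        reason = "residence cell is nodata"
      )
    }
    kept <- sampled[!drop, , drop = FALSE]
    for (g in c("case", "control")) {
      tab <- table(factor(kept$value[kept$group == g], levels = levels_cls))
      counts[, g] <- as.integer(tab)
    }
  }
  structure(counts, class = c("contingency_table", "matrix"),
            exposure = exposure, exclusions = exclusions)
}

#' Assemble a contingency table from known counts
#'
#' For analysing published or externally tabulated counts directly.
#'
#' @param counts matrix (or data frame) of non-negative integer counts,
#'   exposure classes in rows (ordered low to high), groups `case` and
#'   `control` in columns.
#' @param exposure name for the exposure variable.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(counts, exposure = "exposure") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts must be non-negative integers")
  }
  if (is.null(colnames(counts))) colnames(counts) <- c("case", "control")
  if (is.null(rownames(counts))) {
    rownames(counts) <- if (nrow(counts) == 2) c("low", "high") else
      c("low", "moderate", "high")[seq_len(nrow(counts))]
  }
  storage.mode(counts) <- "integer"
  structure(counts,
            class = c("contingency_table", "matrix"),
            exposure = exposure,
            exclusions = tibble::tibble(id = character(), x = numeric(),
                                        y = numeric(), reason = character()))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s\n", attr(x, "exposure")))
  print(unclass(x)[, , drop = FALSE])
  ex <- attr(x, "exclusions")
  if (nrow(ex)) cat(sprintf("%d record(s) excluded (nodata cells)\n", nrow(ex)))
  invisible(x)
}

#' Bundled published exposure counts
#'
#' Case/control counts by exposure class for the six tabulated exposure
#' variables of the source study (susceptibility index, distance to
#' polluting facilities, facility density, distance to major roads, land
#' use, fog proneness), as published. Useful for re-running the
#' contingency analysis on the published numbers.
#'
#' @return A tibble with columns `exposure`, `class`, `case`, `control`.
#' @export
published_exposure_counts <- function() {
  readr::read_csv(
    system.file("extdata", "exposure_counts.csv", package = "smcair",
                mustWork = TRUE),
    col_types = readr::cols(
      exposure = readr::col_character(), class = readr::col_character(),
      case = readr::col_integer(), control = readr::col_integer()
    )
  )
}

#' Contingency tables from a long counts table
#'
#' @param counts tibble with columns `exposure`, `class`, `case`,
#'   `control` (one row per exposure class, ordered low to high).
#' @return Named list of [contingency_table()]s, one per exposure.
#' @export
contingency_from_counts <- function(counts) {
  split(counts, factor(counts$exposure, levels = unique(counts$exposure))) |>
    lapply(function(df) {
      m <- as.matrix(df[, c("case", "control")])
      rownames(m) <- df$class
      contingency_table(m, exposure = df$exposure[1])
    })
}

#' Pearson chi-square test of exposure-group association
#'
#' Pearson's chi-square test of independence on a contingency table, with
#' Yates continuity correction applied automatically to 2x2 tables (and
#' only there), matching common epidemiological software defaults; set
#' `correct = FALSE` to force the uncorrected statistic.
#'
#' @param table a [contingency_table()] (or plain counts matrix).
#' @param correct apply the continuity correction on 2x2 tables
#'   (default TRUE).
#' @return A `chi2_result`: `statistic`, `df`, `p_value`, `correction`.
#' @export
pearson_chi2 <- function(table, correct = TRUE) {
  m <- unclass(as.matrix(table))
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (sum(keep_r) < 2 || sum(keep_c) < 2) {
    bad <- c(rownames(m)[!keep_r], colnames(m)[!keep_c])
    stop_degenerate(sprintf(
      "degenerate table: margin(s) %s are zero, fewer than 2 informative rows/columns",
      paste(if (length(bad)) bad else "(none)", collapse = ", ")
    ))
  }
  m <- m[keep_r, keep_c, drop = FALSE]
  is2x2 <- all(dim(m) == c(2, 2))
  ht <- suppressWarnings(chisq.test(m, correct = correct && is2x2))
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value),
         correction = if (correct && is2x2) "yates" else "none",
         exposure = attr(table, "exposure") %||% "exposure"),
    class = "chi2_result"
  )
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square (%s): X2 = %.3f, df = %d, p = %.3f (%s)\n",
              x$exposure, x$statistic, x$df, x$p_value, x$correction))
  invisible(x)
}

#' @export
tidy.chi2_result <- function(x, ...) {
  tibble::tibble(exposure = x$exposure, statistic = x$statistic,
                 df = x$df, p_value = x$p_value, correction = x$correction)
}

#' @export
glance.chi2_result <- function(x, ...) tidy(x)

#' Suppression-aware frequency report
#'
#' Long-format report of absolute and relative frequencies by exposure
#' class and group. Percentages are of the group (column) total of the
#' tabulated rows, rounded to one decimal. Statistical-secrecy suppression
#' masks cells with absolute frequency strictly below the threshold
#' (default 3): both the count and its percentage are withheld; group
#' totals are unaffected.
#'
#' @param tables a [contingency_table()] or (named) list of them.
#' @param suppression_threshold counts strictly below this are suppressed
#'   (default 3; 0 disables).
#' @return A tibble with columns `exposure`, `class`, `group`, `n`, `pct`,
#'   `suppressed`, `display` (formatted count, `"<threshold"` marker when
#'   suppressed).
#' @export
frequency_report <- function(tables, suppression_threshold = 3) {
  if (suppression_threshold < 0) stop_invalid("`suppression_threshold` must be >= 0")
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  purrr::imap_dfr(tables, function(tab, nm) {
    exposure <- attr(tab, "exposure") %||% (if (is.character(nm)) nm else "exposure")
    m <- unclass(as.matrix(tab))
    totals <- colSums(m)
    purrr::map_dfr(colnames(m), function(g) {
      n <- unname(m[, g])
      pct <- round(100 * n / totals[[g]], 1)
      suppressed <- n < suppression_threshold  # strict "<" per the secrecy rule
      tibble::tibble(
        exposure = exposure,
        class = rownames(m),
        group = g,
        n = ifelse(suppressed, NA_integer_, as.integer(n)),
        pct = ifelse(suppressed, NA_real_, pct),
        suppressed = suppressed,
        display = ifelse(suppressed, sprintf("<%d", suppression_threshold),
                         as.character(n))
      )
    })
  })
}
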