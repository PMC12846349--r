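#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value is computed from the hypergeometric distribution by the
#' point-probability method: with margins fixed, all tables whose point
#' probability does not exceed the observed table's point probability
#' (times a `1 + 1e-7` tolerance factor guarding against floating-point
#' ties) contribute to the two-sided p. The odds ratio is the sample
#' cross-product ratio `(a*d)/(b*c)`, `Inf` when `b*c == 0` and
#' `a*d > 0`, and 1 for a degenerate table with a zero margin.
#'
#' @param table A 2x2 matrix of non-negative counts `rbind(c(a, b),
#'   c(c, d))` (rows: group yes/no; columns: system present/absent), or a
#'   length-4 vector `c(a, b, c, d)`.
#' @return A list with `p` and `odds_ratio`.
#' @export
fisher_exact <- function(table) {
  x <- as.integer(table)
  if (length(x) != 4L || any(x < 0))
    stop("fisher_exact needs four non-negative counts", call. = FALSE)
  a <- x[1L]; b <- x[2L]; cc <- x[3L]; d <- x[4L]
  n <- a + b + cc + d
  if (n == 0L) stop("fisher_exact: all-zero table", call. = FALSE)
  r1 <- a + b; c1 <- a + cc
  # support of the hypergeometric count in cell a with fixed margins
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (r1 == 0L || c1 == 0L || r1 == n || c1 == n) {
    1  # a zero margin carries no association information
  } else if (b * cc == 0) {
    Inf
  } else {
    (a * d) / (b * cc)
  }
  list(p = p, odds_ratio = or)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) m * p_(j) / j` over the ascending sort, capped at
#' 1 and mapped back to input order, controlling the false discovery rate
#' across the screen.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvalues)
  ord <- order(pvalues)
  ranked <- pvalues[ord] * m / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(ranked))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Construct a strain-by-system presence/absence table
#'
#' @param strain_ids Character vector of strain identifiers.
#' @param group Per-strain group label; exactly two levels are required
#'   for enrichment testing.
#' @param matrix Logical strain-by-system matrix with column names naming
#'   the systems.
#' @return A `presence_absence_table`.
#' @export
presence_absence_table <- function(strain_ids, group, matrix) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix)) || ncol(matrix) == 0L)
    stop("matrix must have named system columns", call. = FALSE)
  if (nrow(matrix) != length(strain_ids) ||
      length(group) != length(strain_ids))
    stop("matrix rows, strain_ids and group must align", call. = FALSE)
  structure(list(strain_ids = as.character(strain_ids),
                 group = as.character(group),
                 systems = colnames(matrix),
                 matrix = matrix > 0),
            class = "presence_absence_table")
}

#' Defense-system enrichment screen
#'
#' For each system a 2x2 table of group membership by system presence is
#' tested with [fisher_exact()]; q-values are obtained by [bh_adjust()]
#' across all systems of the screen and called significant at `q < alpha`.
#' The focal group is the first of the two levels sorted alphabetically
#' unless `focal` is given.
#'
#' @param table A [presence_absence_table()].
#' @param alpha Significance level on the adjusted q-values.
#' @param focal Optional group level treated as the focal (first) row.
#' @return A data frame with one row per system: counts `a`, `b`, `c`,
#'   `d` (focal/with, focal/without, other/with, other/without),
#'   `odds_ratio`, `p`, `q`, `significant`.
#' @export
enrichment_screen <- function(table, alpha = 0.05, focal = NULL) {
  stopifnot(inherits(table, "presence_absence_table"))
  levs <- sort(unique(table$group))
  if (length(levs) != 2L)
    stop("enrichment_screen needs exactly two group levels, got ",
         length(levs), call. = FALSE)
  if (is.null(focal)) focal <- levs[1L]
  if (!focal %in% levs) stop("unknown focal group: ", focal, call. = FALSE)
  in_focal <- table$group == focal
  res <- lapply(table$systems, function(sys) {
    present <- table$matrix[, sys]
    a <- sum(in_focal & present); b <- sum(in_focal & !present)
    cc <- sum(!in_focal & present); d <- sum(!in_focal & !present)
    ft <- fisher_exact(c(a, b, cc, d))
    data.frame(system = sys, a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out[order(out$q, out$p, out$system), ]
}

#' Host-range summary by serogroup
#'
#' Counts susceptible and total strains per serogroup, plus an overall
#' row.
#'
#' @param lysis Logical vector: was the strain lysed?
#' @param serogroup Per-strain serogroup label, same length as `lysis`.
#' @return A data frame with `serogroup`, `susceptible`, `total`; the
#'   final row (`"all"`) is the overall summary. Empty input gives a
#'   zero-row frame.
#' @export
host_range_summary <- function(lysis, serogroup) {
  if (length(lysis) != length(serogroup))
    stop("lysis and serogroup must have equal length", call. = FALSE)
  if (length(lysis) == 0L)
    return(data.frame(serogroup = character(), susceptible = integer(),
                      total = integer(), stringsAsFactors = FALSE))
  lysis <- as.logical(lysis)
  tab <- data.frame(
    serogroup = sort(unique(serogroup)),
    stringsAsFactors = FALSE)
  tab$susceptible <- vapply(tab$serogroup, function(g)
    sum(lysis[serogroup == g]), integer(1L))
  tab$total <- vapply(tab$serogroup, function(g)
    sum(serogroup == g), integer(1L))
  rbind(tab, data.frame(serogroup = "all",
                        susceptible = sum(lysis),
                        total = length(lysis),
                        stringsAsFactors = FALSE))
}

#' Read a presence/absence TSV
#'
#' Expects strains as rows with a strain id column, a group column, and
#' one 0/1 (or TRUE/FALSE) column per system — the shape produced by
#' defense-system annotation post-processing.
#'
#' @param path File path.
#' @param id_col,group_col Column names of the strain id and group label.
#' @return A [presence_absence_table()].
#' @export
read_presence_absence <- function(path, id_col = "strain_id",
                                  group_col = "group") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c(id_col, group_col) %in% names(df)))
    stop("table must contain columns '", id_col, "' and '", group_col, "'",
         call. = FALSE)
  sys_cols <- setdiff(names(df), c(id_col, group_col))
  mat <- as.matrix(df[, sys_cols, drop = FALSE])
  storage.mode(mat) <- "logical"
  presence_absence_table(df[[id_col]], df[[group_col]], mat)
}
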