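#' Linear-gap scoring scheme for alignment
#'
#' @param match Score for a matching column (must exceed `mismatch`).
#' @param mismatch Score for a mismatching column.
#' @param gap Linear gap penalty per gapped column (must be negative).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -2) {
  if (!(match > mismatch)) stop("match must exceed mismatch", call. = FALSE)
  if (!(gap < 0)) stop("gap penalty must be negative", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

new_alignment <- function(rows, ids, score = NA_real_) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(list(rows = rows, ids = ids, score = score),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d row(s), %d column(s)", length(x$rows),
              nchar(x$rows[1L])))
  if (!is.na(x$score)) cat(sprintf(", score %g", x$score))
  cat("\n")
  invisible(x)
}

#' Global pairwise alignment (Needleman-Wunsch, linear gaps)
#'
#' Optimal global alignment under a linear gap penalty with deterministic
#' traceback (diagonal preferred over an `a`-consuming gap over a
#' `b`-consuming gap when scores tie).
#'
#' @param a,b Sequences as strings (non-empty).
#' @param scheme A [scoring_scheme()].
#' @return An `Alignment` with two rows (gapped `a` and `b`) and the
#'   optimal `score`.
#' @export
nw_align <- function(a, b, scheme = scoring_scheme()) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("nw_align: sequences must be non-empty", call. = FALSE)
  res <- nw_align_cpp(a, b, scheme$match, scheme$mismatch, scheme$gap)
  new_alignment(c(res$a, res$b), ids = c("a", "b"), score = res$score)
}

#' Center-star progressive multiple sequence alignment
#'
#' The center is the input sequence maximizing the summed pairwise
#' [nw_align()] scores against all others (first such sequence on ties);
#' the remaining sequences are merged into the center's coordinate system
#' under the "once a gap, always a gap" rule. Degapping any output row
#' recovers the corresponding input exactly.
#'
#' @param seqs Character vector (or list) of at least two sequences.
#' @param scheme A [scoring_scheme()].
#' @param ids Row identifiers; defaults to names of `seqs` or `seq1..n`.
#' @return An `Alignment` with one row per input, in input order.
#' @export
star_msa <- function(seqs, scheme = scoring_scheme(), ids = NULL) {
  seqs <- toupper(unlist(seqs, use.names = TRUE))
  n <- length(seqs)
  if (n < 2L) stop("star_msa needs at least two sequences", call. = FALSE)
  if (is.null(ids)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_len(n))
  }

  # summed pairwise scores to pick the center
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- nw_align(seqs[i], seqs[j], scheme)
      scores[i, j] <- scores[j, i] <- al$score
    }
  }
  center <- which.max(rowSums(scores))

  master <- strsplit(seqs[center], "")[[1L]]
  rows <- list(master)          # rows in master coordinates; center first
  order_idx <- center
  for (i in setdiff(seq_len(n), center)) {
    al <- nw_align(seqs[center], seqs[i], scheme)
    cg <- strsplit(al$rows[1L], "")[[1L]]
    sg <- strsplit(al$rows[2L], "")[[1L]]
    merged <- merge_into_master(master, rows, cg, sg)
    master <- merged$master
    rows <- merged$rows
    order_idx <- c(order_idx, i)
  }
  out <- vapply(rows, paste, character(1L), collapse = "")
  out <- out[order(order_idx)]  # back to input order
  new_alignment(out, ids = ids, score = NA_real_)
}

# Merge one pairwise alignment (center row cg, new row sg) into the master
# center gapping, inserting gaps so existing rows stay consistent.
merge_into_master <- function(master, rows, cg, sg) {
  new_master <- character(0)
  new_row <- character(0)
  ins_old <- logical(0)  # per output column: TRUE if existing rows get a gap
  i <- 1L; j <- 1L
  nm <- length(master); nc <- length(cg)
  while (i <= nm || j <= nc) {
    mi <- if (i <= nm) master[i] else NULL
    cj <- if (j <= nc) cg[j] else NULL
    if (!is.null(mi) && mi == "-" && (is.null(cj) || cj != "-")) {
      # master has a gap the pairwise alignment lacks: pad new row
      new_master <- c(new_master, "-"); new_row <- c(new_row, "-")
      ins_old <- c(ins_old, FALSE); i <- i + 1L
    } else if (!is.null(cj) && cj == "-" && (is.null(mi) || mi != "-")) {
      # pairwise alignment opens a gap in the center: pad existing rows
      new_master <- c(new_master, "-"); new_row <- c(new_row, sg[j])
      ins_old <- c(ins_old, TRUE); j <- j + 1L
    } else {
      # both gap, or both the same residue
      new_master <- c(new_master, mi); new_row <- c(new_row, sg[j])
      ins_old <- c(ins_old, FALSE); i <- i + 1L; j <- j + 1L
    }
  }
  rows <- lapply(rows, function(r) {
    out <- character(length(ins_old)); k <- 1L
    for (col in seq_along(ins_old)) {
      if (ins_old[col]) out[col] <- "-"
      else { out[col] <- r[k]; k <- k + 1L }
    }
    out
  })
  rows[[length(rows) + 1L]] <- new_row
  list(master = new_master, rows = rows)
}

#' Pairwise percent identity of two gapped alignment rows
#'
#' `100 * matches / (columns where at least one row is non-gap)`; columns
#' gapped in both rows are excluded from the denominator.
#'
#' @param a_row,b_row Gapped rows of equal length.
#' @return Identity percentage.
#' @export
pairwise_identity <- function(a_row, b_row) {
  if (nchar(a_row) != nchar(b_row))
    stop("rows must have equal length", call. = FALSE)
  a <- strsplit(toupper(a_row), "")[[1L]]
  b <- strsplit(toupper(b_row), "")[[1L]]
  scored <- a != "-" | b != "-"
  if (!any(scored))
    stop("pairwise_identity undefined for an all-gap pair", call. = FALSE)
  100 * sum(a == b & a != "-" & scored) / sum(scored)
}

#' Column conservation statistics of a multiple alignment
#'
#' An invariant column holds one unique non-gap symbol and no gaps across
#' all rows. `min_pairwise_identity` is the minimum of
#' [pairwise_identity()] over all row pairs.
#'
#' @param msa An `Alignment` with at least two rows.
#' @return A list with `n_columns`, `invariant_fraction`,
#'   `min_pairwise_identity` and `column_frequencies` (symbol-by-column
#'   relative frequency matrix over non-gap symbols).
#' @export
conservation_profile <- function(msa) {
  rows <- msa$rows
  if (length(rows) < 2L)
    stop("conservation_profile needs at least two rows", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  nc <- ncol(mat)
  invariant <- apply(mat, 2L, function(col) {
    !any(col == "-") && length(unique(col)) == 1L
  })
  symbols <- sort(setdiff(unique(as.vector(mat)), "-"))
  freq <- vapply(seq_len(nc), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) return(setNames(rep(0, length(symbols)), symbols))
    tab <- table(factor(col, levels = symbols))
    as.numeric(tab) / length(col)
  }, numeric(length(symbols)))
  freq <- matrix(freq, nrow = length(symbols), ncol = nc,
                 dimnames = list(symbols, NULL))
  pairs <- utils::combn(length(rows), 2L)
  min_pid <- min(vapply(seq_len(ncol(pairs)), function(k) {
    pairwise_identity(rows[pairs[1L, k]], rows[pairs[2L, k]])
  }, numeric(1L)))
  list(n_columns = nc,
       invariant_fraction = mean(invariant),
       min_pairwise_identity = min_pid,
       column_frequencies = freq)
}

#' Write a (gapped) alignment as FASTA
#' @param msa An `Alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(msa$rows)) {
    writeLines(paste0(">", msa$ids[i]), con)
    writeLines(msa$rows[i], con)
  }
  invisible(path)
}
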