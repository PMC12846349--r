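#' Construct a genome record
#'
#' A `GenomeRecord` bundles a nucleotide sequence with strand-aware feature
#' coordinates. Coordinates are 0-based half-open throughout the package;
#' GenBank/GFF3 1-based inclusive coordinates are converted at I/O time.
#'
#' @param id Record identifier (e.g. an accession).
#' @param sequence Nucleotide sequence as a single string; coerced to
#'   uppercase. IUPAC ambiguity codes and `N` are allowed.
#' @param features A data frame of features with columns `feature_id`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`) and `kind`
#'   (`"CDS"` or `"other"`), or `NULL` for none.
#' @param source Free-text provenance (file path or accession).
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(id, sequence, features = NULL, source = "") {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("genome_record: sequence must be a non-empty string", call. = FALSE)
  if (grepl("[^ACGTNRYSWKMBDHV]", sequence))
    stop("genome_record: sequence contains non-IUPAC characters", call. = FALSE)
  features <- validate_features(features, nchar(sequence))
  structure(
    list(id = as.character(id), sequence = sequence,
         features = features, source = as.character(source)),
    class = "GenomeRecord"
  )
}

empty_features <- function() {
  data.frame(feature_id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, genome_len) {
  if (is.null(features) || nrow(features) == 0L) return(empty_features())
  needed <- c("feature_id", "start", "end", "strand", "kind")
  if (!all(needed %in% names(features)))
    stop("features must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  features <- features[, needed]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 0L) || any(features$start >= features$end) ||
      any(features$end > genome_len))
    stop("feature intervals must satisfy 0 <= start < end <= genome length",
         call. = FALSE)
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'", call. = FALSE)
  rownames(features) <- NULL
  features
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s: %d bp, %d feature(s)  [%s]\n",
              x$id, nchar(x$sequence), nrow(x$features), x$source))
  invisible(x)
}

#' Read genome records from FASTA or GenBank flat files
#'
#' FASTA parsing is delegated to Biostrings; GenBank flat files are parsed
#' with a minimal reader that understands `LOCUS`, `FEATURES` (plain and
#' `complement()` locations with `/locus_tag` qualifiers) and `ORIGIN`
#' blocks — the subset this package writes and consumes. GenBank 1-based
#' inclusive coordinates are converted to 0-based half-open on read.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"genbank"`.
#' @return A list of [genome_record()] objects, one per sequence entry.
#' @export
read_genomes <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- switch(format,
    fasta = read_genomes_fasta(path),
    genbank = read_genomes_genbank(path)
  )
  if (length(recs) == 0L)
    stop("no sequence records found in ", path, call. = FALSE)
  recs
}

read_genomes_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), source = path)
  })
}

read_genomes_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0L) return(list())
  end_at <- grep("^//\\s*$", lines)
  if (length(end_at) < length(locus_at))
    stop("GenBank parse error in ", path,
         ": record starting at line ", locus_at[length(end_at) + 1L],
         " has no terminating '//'", call. = FALSE)
  lapply(seq_along(locus_at), function(i) {
    block <- lines[locus_at[i]:end_at[end_at > locus_at[i]][1L]]
    parse_genbank_record(block, path, locus_at[i])
  })
}

parse_genbank_record <- function(block, path, line0) {
  id <- strsplit(trimws(sub("^LOCUS", "", block[1L])), "\\s+")[[1L]][1L]
  ori <- grep("^ORIGIN", block)
  if (length(ori) != 1L)
    stop("GenBank parse error in ", path, " (record at line ", line0,
         "): missing ORIGIN block", call. = FALSE)
  seq_lines <- block[(ori + 1L):length(block)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L)
    stop("GenBank parse error in ", path, " (record at line ", line0,
         "): empty ORIGIN sequence", call. = FALSE)

  feats <- empty_features()
  fstart <- grep("^FEATURES", block)
  if (length(fstart) == 1L) {
    fl <- block[(fstart + 1L):(ori - 1L)]
    key_at <- grep("^ {5}\\S", fl)
    for (k in seq_along(key_at)) {
      from <- key_at[k]
      to <- if (k < length(key_at)) key_at[k + 1L] - 1L else length(fl)
      entry <- fl[from:to]
      kv <- strsplit(trimws(entry[1L]), "\\s+")[[1L]]
      key <- kv[1L]
      if (key == "source") next
      loc <- paste(kv[-1L], collapse = "")
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      loc <- gsub("^complement\\(|\\)$", "", loc)
      m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1L]]
      if (length(m) != 3L)
        stop("GenBank parse error in ", path, " (record at line ", line0,
             "): unsupported location '", loc, "'", call. = FALSE)
      start1 <- as.integer(m[2L]); end1 <- as.integer(m[3L])
      tagm <- regmatches(entry, regexec("/locus_tag=\"([^\"]+)\"", entry))
      tag <- unlist(lapply(tagm, function(z) if (length(z) == 2L) z[2L]))
      fid <- if (length(tag) >= 1L) tag[1L] else
        sprintf("%s_%s_%d_%d", id, key, start1, end1)
      feats <- rbind(feats, data.frame(
        feature_id = fid, start = start1 - 1L, end = end1,
        strand = strand, kind = if (key == "CDS") "CDS" else "other",
        stringsAsFactors = FALSE))
    }
  }
  genome_record(id, sequence, feats, source = path)
}

#' Write genome records as a GenBank flat file
#'
#' Emits the minimal GenBank subset [read_genomes()] parses back: `LOCUS`,
#' `FEATURES` with plain or `complement()` single-interval locations and
#' `/locus_tag` qualifiers, and an `ORIGIN` block. Re-reading reproduces
#' the feature table exactly (coordinate round-trip).
#'
#' @param records A `GenomeRecord` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "GenomeRecord")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    n <- nchar(rec$sequence)
    writeLines(sprintf(
      "LOCUS       %s %d bp    DNA     linear   PHG", rec$id, n), con)
    writeLines(sprintf("DEFINITION  %s.", rec$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    if (nrow(rec$features) > 0L) {
      for (j in seq_len(nrow(rec$features))) {
        f <- rec$features[j, ]
        key <- if (f$kind == "CDS") "CDS" else "misc_feature"
        loc <- sprintf("%d..%d", f$start + 1L, f$end)
        if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     %-16s%s", key, loc), con)
        writeLines(sprintf("                     /locus_tag=\"%s\"",
                           f$feature_id), con)
      }
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, n, by = 60L)
    for (p in pos) {
      starts <- seq(p, min(p + 59L, n), by = 10L)
      chunk <- substring(rec$sequence, starts, pmin(starts + 9L, n))
      writeLines(sprintf("%9d %s", p, tolower(paste(chunk, collapse = " "))),
                 con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' GC content of a genome, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`. `N` and other ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param x A `GenomeRecord` or a nucleotide string.
#' @return GC percentage (scalar).
#' @export
gc_content <- function(x) {
  counts <- acgt_counts(x)
  tot <- sum(counts)
  if (tot == 0L)
    stop("gc_content undefined: no unambiguous A/C/G/T bases", call. = FALSE)
  100 * (counts[["G"]] + counts[["C"]]) / tot
}

#' AT content of a genome, in percent
#'
#' Complement of [gc_content()] over the unambiguous bases, so
#' `gc_content(x) + at_content(x) == 100`.
#'
#' @inheritParams gc_content
#' @return AT percentage (scalar).
#' @export
at_content <- function(x) {
  counts <- acgt_counts(x)
  tot <- sum(counts)
  if (tot == 0L)
    stop("at_content undefined: no unambiguous A/C/G/T bases", call. = FALSE)
  100 * (counts[["A"]] + counts[["T"]]) / tot
}

acgt_counts <- function(x) {
  s <- if (inherits(x, "GenomeRecord")) x$sequence else toupper(as.character(x))
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
  freq[c("A", "C", "G", "T")]
}

#' Detect a direct terminal repeat (DTR) border
#'
#' Finds the longest `k <= floor(length/2)` for which the k-nt prefix of the
#' sequence equals its k-nt suffix, by exact matching (a border in the
#' string sense, computed with the Knuth-Morris-Pratt failure function).
#' This detects the repeat border in an assembly where the terminal repeat
#' is present at both ends; it does not reimplement read-coverage terminus
#' typing.
#'
#' @param record A `GenomeRecord` or nucleotide string.
#' @param min_len Minimum repeat length to report as found (nt).
#' @return A list with `repeat_length`, `unique_length` and `found`.
#' @export
detect_dtr <- function(record, min_len = 20L) {
  s <- if (inherits(record, "GenomeRecord")) record$sequence
       else toupper(as.character(record))
  n <- nchar(s)
  if (n < 2L * min_len)
    stop("sequence shorter than 2 * min_len", call. = FALSE)
  # longest border (prefix == suffix) <= floor(n/2); a longer border can
  # exist (e.g. "ababa"), so the KMP failure chain is followed, not capped
  k <- kmp_border_cpp(s, n %/% 2L)
  found <- k >= min_len
  list(repeat_length = as.integer(k),
       unique_length = as.integer(if (found) n - k else n),
       found = found)
}

#' Extract open reading frames on both strands
#'
#' Reports all maximal ORFs running from an allowed start codon to the first
#' in-frame stop (`TAA`/`TAG`/`TGA`), at least `min_aa` codons long
#' (stop excluded). Per stop-anchored frame the leftmost (longest) start is
#' reported. Minus-strand ORFs are found on the reverse complement and
#' mapped back to genome coordinates with `strand = "-"`. Coordinates
#' include the stop codon.
#'
#' @param record A `GenomeRecord` or nucleotide string.
#' @param min_aa Minimum protein length in codons (default 30).
#' @param starts Allowed start codons.
#' @return A feature data frame (`feature_id`, `start`, `end`, `strand`,
#'   `kind = "CDS"`), 0-based half-open genome coordinates.
#' @export
extract_orfs <- function(record, min_aa = 30L,
                         starts = c("ATG", "GTG", "TTG")) {
  s <- if (inherits(record, "GenomeRecord")) record$sequence
       else toupper(as.character(record))
  n <- nchar(s)
  plus <- orfs_one_strand(s, min_aa, starts)
  rc <- revcomp(s)
  minus <- orfs_one_strand(rc, min_aa, starts)
  if (nrow(minus) > 0L) {
    gs <- n - minus$end
    ge <- n - minus$start
    minus$start <- gs
    minus$end <- ge
    minus$strand <- "-"
  }
  out <- rbind(plus, minus)
  if (nrow(out) > 0L) {
    out$feature_id <- sprintf("orf_%d_%d_%s", out$start + 1L, out$end,
                              ifelse(out$strand == "+", "p", "m"))
    out <- out[order(out$start, out$end, out$strand), ]
    rownames(out) <- NULL
  }
  out
}

orfs_one_strand <- function(s, min_aa, starts) {
  n <- nchar(s)
  res <- list()
  for (frame in 0:2) {
    if (n - frame < 6L) next
    at <- seq(frame + 1L, n - 2L, by = 3L)
    cods <- substring(s, at, at + 2L)
    is_stop <- cods %in% c("TAA", "TAG", "TGA")
    is_start <- cods %in% starts
    prev_stop <- 0L
    for (si in which(is_stop)) {
      cand <- which(is_start[(prev_stop + 1L):(si - 1L)])
      if (length(cand) > 0L) {
        m <- prev_stop + cand[1L]
        if ((si - m) >= min_aa) {
          res[[length(res) + 1L]] <- c(at[m] - 1L, at[si] + 2L)
        }
      }
      prev_stop <- si
    }
  }
  if (length(res) == 0L) return(empty_features())
  mat <- do.call(rbind, res)
  data.frame(feature_id = "", start = mat[, 1L], end = mat[, 2L],
             strand = "+", kind = "CDS", stringsAsFactors = FALSE)
}

#' Reverse complement of a nucleotide string
#' @param s Nucleotide string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Whole-genome summary statistics
#'
#' Convenience wrapper computing length, GC content and the DTR border for
#' one or more records.
#'
#' @param records A `GenomeRecord` or list of them.
#' @param min_dtr Minimum DTR length passed to [detect_dtr()].
#' @return A data frame with one row per record.
#' @export
genome_stats <- function(records, min_dtr = 20L) {
  if (inherits(records, "GenomeRecord")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    d <- detect_dtr(r, min_len = min_dtr)
    data.frame(id = r$id, length_bp = nchar(r$sequence),
               gc_percent = gc_content(r),
               dtr_length = d$repeat_length,
               unique_length = d$unique_length,
               dtr_found = d$found, stringsAsFactors = FALSE)
  }))
}
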