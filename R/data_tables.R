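#' Reference local-virulence ladder of phage Adele
#'
#' Measured local virulence of *Pseudomonas* phage Adele infecting
#' *P. aeruginosa* PAO1 across an eight-step MOI ladder (10^-7 to 1),
#' from a dynamic killing assay read every 30 min. Shipped as a small
#' TSV so the integrated virulence index can be recomputed from the
#' published per-MOI values:
#' `virulence_index(adele_local_virulence())` gives 0.536.
#'
#' @return A data frame with columns `moi` and `v`.
#' @export
adele_local_virulence <- function() {
  path <- system.file("extdata", "adele_local_virulence.tsv",
                      package = "phagechar", mustWork = TRUE)
  df <- read.delim(path)
  data.frame(moi = df$moi, v = df$local_virulence)
}

#' Reference host-range panel of phage Adele, by serogroup
#'
#' Lysis outcomes of phage Adele against serotyped *P. aeruginosa*
#' isolates: the single O1 isolate, one of three O3, three of five O5 and
#' three of eight O6 isolates were lysed; the single O2 isolate and all
#' eight O11 isolates were not.
#'
#' @return A data frame with per-strain `serogroup` and `lysis` columns
#'   suitable for [host_range_summary()].
#' @export
adele_host_range <- function() {
  counts <- data.frame(
    serogroup = c("O1", "O2", "O3", "O5", "O6", "O11"),
    susceptible = c(1L, 0L, 1L, 3L, 3L, 0L),
    total = c(1L, 1L, 3L, 5L, 8L, 8L))
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$total[i]; k <- counts$susceptible[i]
    data.frame(serogroup = rep(counts$serogroup[i], n),
               lysis = seq_len(n) <= k)
  }))
}
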