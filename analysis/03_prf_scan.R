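#!/usr/bin/env Rscript

# Stage 3: -1 programmed ribosomal frameshift survey of the tail assembly
# chaperone locus across the genome set: slippery-motif search in the 3'
# window, -1 read-through measurement, allele deduplication, center-star
# alignment and conservation statistics, plus whole-genome stats (GC,
# terminal repeat border).

suppressPackageStartupMessages(library(phagechar))

dat <- "results/data"
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genomes <- read_genomes(file.path(dat, "prf_genomes.gbk"), "genbank")
locus_map <- read.delim(file.path(dat, "prf_locus_map.tsv"))
truth <- read.delim(file.path(dat, "prf_truth.tsv"))

stats <- genome_stats(genomes, min_dtr = 20)
write.table(stats, file.path(out, "genome_stats.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("genomes: %d, mean GC %.1f%%, DTR border %d nt in all\n",
            nrow(stats), mean(stats$gc_percent),
            unique(stats$dtr_length)))

sv <- survey_locus(genomes, locus_map, threshold_nt = 200)
write.table(sv$per_genome, file.path(out, "prf_results.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("PRF survey: %d/%d genomes pass (motif + stop-free -1 extension >= 200 nt)\n",
            sum(sv$per_genome$passes), sv$n_genomes))
cat(sprintf("unique alleles: %d of %d genomes\n", sv$n_unique_alleles,
            sv$n_genomes))

agree <- identical(sv$per_genome$passes, truth$expected_pass)
cat(sprintf("agreement with generator ground truth: %s\n",
            if (agree) "exact" else "MISMATCH"))

if (!is.null(sv$msa)) {
  write_alignment_fasta(sv$msa, file.path(out, "prf_alleles_msa.fasta"))
  prof <- sv$conservation
  cons <- data.frame(n_columns = prof$n_columns,
                     invariant_fraction = prof$invariant_fraction,
                     min_pairwise_identity = prof$min_pairwise_identity)
  write.table(cons, file.path(out, "prf_conservation.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat(sprintf("allele MSA: %d columns, %.1f%% invariant, minimum identity %.1f%%\n",
              prof$n_columns, 100 * prof$invariant_fraction,
              prof$min_pairwise_identity))
}
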