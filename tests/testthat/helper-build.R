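# Builders for small hand-constructed fixtures used across test files.

# phylo_classes-like structure from a list of patterns (character vectors);
# each class gets `members_per` synthetic member SNV ids
make_classes <- function(patterns, samples, members_per = 2L,
                         status = "robust") {
  k <- 0L
  cls <- lapply(seq_along(patterns), function(i) {
    members <- sprintf("snv%03d", k + seq_len(members_per))
    k <<- k + members_per
    list(class_id = sprintf("c%03d", i), pattern = sort(patterns[[i]]),
         members = members, status = status)
  })
  structure(cls, class = "phylo_classes", samples = samples)
}

# vaf_matrix with the given values (SNV x sample), full depth
make_vafm <- function(values, depth = 10000L) {
  depths <- matrix(as.integer(depth), nrow(values), ncol(values),
                   dimnames = dimnames(values))
  new_vaf_matrix(values, depths)
}

# count table row helper
count_row <- function(patient, snv, sample, A = 0L, C = 0L, G = 0L, T = 0L) {
  data.frame(patient_id = patient, snv_id = snv, sample_id = sample,
             A = A, C = C, G = G, T = T)
}

as_count_table <- function(...) {
  df <- do.call(rbind, list(...))
  class(df) <- c("allele_count_table", "data.frame")
  df
}

make_sites <- function(snv_ids, ref = "A", alt = "G", is_hotspot = FALSE) {
  df <- data.frame(snv_id = snv_ids, chrom = "1",
                   pos = seq_along(snv_ids) * 1000, ref = ref, alt = alt,
                   is_hotspot = is_hotspot)
  class(df) <- c("snv_sites", "data.frame")
  df
}

write_tsv_tmp <- function(df, name = "f.tsv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
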