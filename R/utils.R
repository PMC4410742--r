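# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

NUCLEOTIDES <- c("A", "C", "G", "T")

HISTOLOGIES <- c("normal", "lymph_control", "apocrine_metaplasia", "UDH",
                 "CCL", "AH", "FEA", "DCIS", "IDC", "metastasis")

SIDES <- c("ipsilateral", "contralateral", "unknown")

# Canonical string key for a set of sample/component ids. \x1f never occurs in
# ids (validated at read time), so keys are collision-free.
pat_key <- function(p) paste(sort(unique(as.character(p))), collapse = "\x1f")

pat_from_key <- function(k) {
  if (identical(k, "")) return(character(0))
  strsplit(k, "\x1f", fixed = TRUE)[[1]]
}

fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_ids <- function(ids, what) {
  ids <- as.character(ids)
  bad <- grepl("[\x1f\t\n,()\\[\\];=]", ids)
  if (any(bad)) {
    fail("%s contains characters not allowed in identifiers: %s",
         what, paste(unique(ids[bad]), collapse = ", "))
  }
  ids
}

# Population standard deviation; classes are small, so the n denominator is the
# documented convention.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
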