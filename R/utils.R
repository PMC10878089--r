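# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

# package-local cache (genetic-code tables, NG86 lookup tables)
.cache <- new.env(parent = emptyenv())

.asChar <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) as.character(x) else as.character(x)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.geneticCode <- function(codeTable = "4") {
  key <- paste0("gc_", codeTable)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- Biostrings::getGeneticCode(as.character(codeTable))
  }
  .cache[[key]]
}

# split a nucleotide string into codon triplets (drops trailing partial codon)
.codons <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# GC proportion of a character sequence; N (and other ambiguity) excluded
# from the denominator; NA when no unambiguous base is present
.gc <- function(s) {
  if (!nzchar(s)) return(NA_real_)
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  acgt <- v %in% .BASES
  if (!any(acgt)) return(NA_real_)
  sum(v %in% c("G", "C")) / sum(acgt)
}

# random sequence with a given GC proportion
.randSeq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# positional disambiguation of duplicate labels: x, x -> x_a, x_b
.disambiguate <- function(labels) {
  dup <- unique(labels[duplicated(labels)])
  for (lab in dup) {
    idx <- which(labels == lab)
    labels[idx] <- paste0(lab, "_", letters[seq_along(idx)])
  }
  labels
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
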