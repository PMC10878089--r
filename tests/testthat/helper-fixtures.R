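# In-code fixture builders shared across test files.

toyGenome <- function(id = "toy", seq = "ATGCATGCAT", feats = NULL) {
  Mitogenome(id, seq, feats)
}

featRow <- function(gene, category, start, end, strand = "+") {
  data.frame(gene = gene, category = category, start = start, end = end,
             strand = strand)
}

# write a minimal GFF3 by hand (independent of the package writer)
writeToyGff <- function(path, contig, rows) {
  lines <- c("##gff-version 3",
             vapply(rows, function(r)
               paste(contig, "test", r$type, r$start, r$end, ".", r$strand,
                     ".", paste0("ID=", r$id, ";Name=", r$name),
                     sep = "\t"), character(1)))
  writeLines(lines, path)
  path
}

writeToyFasta <- function(path, id, seq) {
  writeLines(c(paste0(">", id), seq), path)
  path
}

# deterministic random DNA
randomDna <- function(n, seed = 1, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcompChar <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
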