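# let-7a-style mature miRNA; seed (bases 2-7) GAGGUA, bases 2-8 GAGGUAG.
LET7 <- c(let7 = "UGAGGUAGUAGGUUGUAUAGUU")
SITE_8MER <- "CTACCTCA"   # revcomp(GAGGTAG) + A
SITE_7M8 <- "CTACCTC"     # revcomp(GAGGTAG)
SITE_7A1 <- "TACCTCA"     # revcomp(GAGGTA) + A

# Naive position-by-position re-scan used as the brute-force oracle.
oracle_scan <- function(target, mirna) {
  mirna <- chartr("uU", "tT", toupper(mirna))
  target <- chartr("uU", "tT", toupper(target))
  s8 <- paste0(revcomp(substr(mirna, 2, 8)), "A")
  s7m8 <- revcomp(substr(mirna, 2, 8))
  s7a1 <- paste0(revcomp(substr(mirna, 2, 7)), "A")
  hits <- list()
  for (p in seq_len(nchar(target) - 6L)) {
    w8 <- substr(target, p, p + 7L)
    w7 <- substr(target, p, p + 6L)
    if (grepl("[^ACGT]", w8)) next
    type <- if (w8 == s8) "8mer"
      else if (w7 == s7m8) "7mer-m8"
      else if (w7 == s7a1) "7mer-A1"
      else NA_character_
    if (!is.na(type)) hits[[length(hits) + 1L]] <- c(pos = p - 1L, type = type)
  }
  hits
}

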