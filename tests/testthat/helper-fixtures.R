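# Builders used across the suite. All fixtures are constructed in code.

# A minimal association data.frame; alleles default to a non-palindromic
# pair so harmonization is the identity unless a test perturbs it.
assocDf <- function(id, beta, se, pval = 1e-10, eaf = 0.3, n = 10000L,
                    ea = "A", oa = "G", chromosome = "1",
                    position = seq_along(id) * 2e7) {
  data.frame(variant_id = id, chromosome = chromosome, position = position,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, pval = pval, n = n, stringsAsFactors = FALSE)
}

makeTable <- function(..., traitLabel = "trait", traitType = "continuous") {
  AssociationTable(assocDf(...), traitLabel = traitLabel,
                   traitType = traitType)
}

# Harmonized instruments straight from effect vectors.
makeH <- function(bx, by, seOut, seExp = rep(1e-6, length(bx)),
                  eafExp = rep(0.3, length(bx)),
                  eafOut = rep(0.3, length(bx)),
                  nExp = rep(10000L, length(bx)),
                  nOut = rep(10000L, length(bx))) {
  k <- length(bx)
  HarmonizedInstruments(data.frame(
    variant_id = sprintf("v%02d", seq_len(k)),
    beta_exp = bx, se_exp = seExp, eaf_exp = eafExp, n_exp = nExp,
    pval_exp = rep(1e-10, k),
    beta_out = by, se_out = seOut, eaf_out = eafOut, n_out = nOut,
    pval_out = rep(0.5, k), stringsAsFactors = FALSE))
}

# Rebuild the two AssociationTables encoded in a HarmonizedInstruments
# object, used to check that harmonization is idempotent.
tablesFromHarmonized <- function(h) {
  d <- instruments(h)
  side <- function(prefix, type) {
    AssociationTable(data.frame(
      variant_id = d$variant_id, chromosome = d$chromosome,
      position = d$position, effect_allele = d$effect_allele,
      other_allele = d$other_allele, eaf = d[[paste0("eaf_", prefix)]],
      beta = d[[paste0("beta_", prefix)]], se = d[[paste0("se_", prefix)]],
      pval = d[[paste0("pval_", prefix)]], n = d[[paste0("n_", prefix)]],
      stringsAsFactors = FALSE), traitType = type)
  }
  list(exposure = side("exp", "binary"), outcome = side("out", "continuous"))
}

writeTempTsv <- function(df, headers = names(df)) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  names(df) <- headers
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

selectQuiet <- function(...) suppressWarnings(selectInstruments(...))
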