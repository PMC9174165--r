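# Synthetic reconstruction of the TREM2 per-tool deleteriousness call matrix.
#
# The original 228-SNP x 17-tool call matrix is not publicly deposited; this
# generator builds a synthetic stand-in that reproduces every published
# summary of it: 228 missense SNPs scored by the 17 named predictors; exactly
# three SNPs -- rs549402254 (W50S), rs749358844 (R52C) and rs1409131974
# (D104G) -- called deleterious by at least 15 tools; DANN calling the most
# SNPs deleterious and FATHMM/MetaLR the fewest; and FATHMM and VEST3
# correlating negatively with the other tools. Individual calls for the other
# 225 SNPs are synthetic and carry no biological meaning.

TREM2_TOOLS <- c("SIFT", "PolyPhen", "Condel", "CADD", "DANN", "FATHMM",
                 "M-CAP", "MetaLR", "MutPred", "MutationAssessor", "PROVEAN",
                 "VEST3", "fathmm-MKL", "MuPro", "iStable", "PhD-SNP",
                 "SNAP2")

TREM2_HIGH_RISK <- c("rs549402254", "rs749358844", "rs1409131974")

#' Synthetic TREM2 predictor call table
#'
#' Deterministic, seeded stand-in for the unpublished 228 x 17 call matrix
#' (see file-level notes for the published facts it reproduces). The three
#' known high-risk SNPs receive 17, 16 and 15 votes; every other SNP is capped
#' below the 15-vote threshold.
#'
#' @param seed integer seed (default 20220601)
#' @return a \code{vd_call_table} with 228 SNPs and 17 tools
#' @export
synth_trem2_call_table <- function(seed = 20220601L) {
  n_snps <- 228L
  tools <- TREM2_TOOLS
  k <- length(tools)
  # per-tool sensitivity to a latent per-SNP deleteriousness propensity;
  # DANN most permissive, FATHMM and MetaLR most conservative
  sens <- c(SIFT = 0.55, PolyPhen = 0.60, Condel = 0.50, CADD = 0.65,
            DANN = 0.92, FATHMM = 0.16, `M-CAP` = 0.55, MetaLR = 0.14,
            MutPred = 0.45, MutationAssessor = 0.50, PROVEAN = 0.55,
            VEST3 = 0.30, `fathmm-MKL` = 0.60, MuPro = 0.55, iStable = 0.50,
            `PhD-SNP` = 0.45, SNAP2 = 0.60)[tools]
  # FATHMM and VEST3 call against the consensus propensity (negative
  # correlation with the other tools)
  inverted <- tools %in% c("FATHMM", "VEST3")
  calls <- with_seed(seed, {
    # U-shaped latent propensity per SNP: wide spread so inter-tool
    # agreement is visible in the phi matrix
    u <- stats::rbeta(n_snps, 0.45, 0.65)
    p <- outer(u, sens)
    p[, inverted] <- outer(1 - u, sens[inverted])
    m <- matrix(stats::rbinom(n_snps * k, 1L, pmin(as.vector(p), 1)),
                n_snps, k)
    # enforce the published consensus facts: the three high-risk SNPs at
    # 17/16/15 votes (rows 1-3), all other SNPs strictly below 15
    m[1, ] <- 1L
    m[2, ] <- 1L; m[2, match("FATHMM", tools)] <- 0L
    m[3, ] <- 1L; m[3, match(c("FATHMM", "VEST3"), tools)] <- 0L
    for (s in 4:n_snps) {
      over <- sum(m[s, ]) - 14L
      if (over > 0L) {
        on <- which(m[s, ] == 1L)
        m[s, sample(on, over)] <- 0L
      }
    }
    m
  })
  ids <- c(TREM2_HIGH_RISK,
           sprintf("rs9%08d", seq_len(n_snps - 3L) * 37L + 100003L))
  call_table(ids, tools, calls)
}
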