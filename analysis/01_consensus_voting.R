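#!/usr/bin/env Rscript
# Stage 1: consensus deleteriousness voting across 17 variant-effect
# predictors for the 228 TREM2 missense SNPs.
#
# Uses the synthetic reconstruction of the per-tool call matrix shipped with
# the package (the original matrix is not publicly deposited; the synthetic
# table reproduces its published summaries). Applies the >= 15-of-17 rule,
# and writes vote counts plus the pairwise tool-agreement (phi) matrix.

library(vardyn)

out <- file.path("results", "consensus")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tab <- read_call_table(system.file("extdata", "trem2_calls_synthetic.csv",
                                   package = "vardyn"))
vc <- vote_counts(tab)
write.csv(vc[order(-vc$votes, vc$snp_id), ],
          file.path(out, "vote_counts.csv"), row.names = FALSE)

high_risk <- filter_high_risk(tab, threshold = 15L)
writeLines(high_risk, file.path(out, "high_risk_snps.txt"))

am <- agreement_matrix(tab)
write.csv(am$r, file.path(out, "tool_agreement_phi.csv"))

per_tool <- colSums(tab$calls)
write.csv(data.frame(tool = names(per_tool), n_deleterious = per_tool),
          file.path(out, "per_tool_totals.csv"), row.names = FALSE)

cat(sprintf("Scored %d SNPs across %d tools.\n", nrow(tab$calls),
            ncol(tab$calls)))
cat(sprintf("High-risk SNPs (>= 15 votes): %s\n",
            paste(high_risk, collapse = ", ")))
cat(sprintf("Most permissive tool: %s (%d calls); most conservative: %s.\n",
            names(which.max(per_tool)), max(per_tool),
            paste(names(sort(per_tool)[1:2]), collapse = " and ")))
offd <- am$r; diag(offd) <- NA
neg <- names(which(rowMeans(offd, na.rm = TRUE) < 0))
cat(sprintf("Tools correlating negatively with the consensus: %s\n",
            paste(neg, collapse = ", ")))
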