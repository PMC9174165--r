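# Consensus aggregation of per-tool deleteriousness calls.
#
# Heterogeneous variant-effect predictors (SIFT, PolyPhen, CADD, ...) are
# reduced to binary deleterious/neutral calls per SNP; consensus voting counts
# how many tools agree, a high-risk threshold (>= 15 of 17 in the reference
# design) selects candidates, and a pairwise phi-coefficient matrix summarises
# inter-tool agreement. Missing calls (a tool did not score a variant) are
# excluded from counts and correlations rather than imputed.

#' Read a call table from CSV/TSV
#'
#' First column: SNP identifier; remaining columns: one per tool with values
#' 0, 1 or NA.
#'
#' @param path file path
#' @param sep field separator (default \code{","})
#' @return a \code{vd_call_table}
#' @export
read_call_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  call_table(df[[1]], colnames(df)[-1],
             as.matrix(df[, -1, drop = FALSE]))
}

#' Write a call table to CSV
#' @param table a \code{vd_call_table}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_call_table <- function(table, path) {
  df <- data.frame(snp_id = table$snp_ids, table$calls, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-SNP deleterious vote counts
#'
#' Number of tools calling each SNP deleterious; missing calls are excluded
#' from the count and reported separately.
#'
#' @param table a \code{vd_call_table}
#' @return data.frame with \code{snp_id}, \code{votes}, \code{n_called}
#'   (tools with a non-missing call)
#' @export
vote_counts <- function(table) {
  if (!inherits(table, "vd_call_table") || nrow(table$calls) == 0L) {
    vd_error("empty or invalid call table", "vardyn_value_error")
  }
  data.frame(snp_id = table$snp_ids,
             votes = as.integer(rowSums(table$calls, na.rm = TRUE)),
             n_called = as.integer(rowSums(!is.na(table$calls))),
             stringsAsFactors = FALSE)
}

#' High-risk SNPs by consensus threshold
#'
#' SNPs called deleterious by at least \code{threshold} tools, ordered by
#' descending vote count with lexicographic SNP-id tie-break. The default of
#' 15 (of 17 tools) is the rule that selects the three high-risk TREM2
#' variants.
#'
#' @param table a \code{vd_call_table}
#' @param threshold minimum vote count (default 15)
#' @return character vector of SNP ids
#' @export
filter_high_risk <- function(table, threshold = 15L) {
  k <- length(table$tool_names)
  if (threshold <= 0L || threshold > k) {
    vd_error(sprintf("threshold must be in 1..%d", k), "vardyn_value_error")
  }
  vc <- vote_counts(table)
  hit <- vc[vc$votes >= threshold, , drop = FALSE]
  hit <- hit[order(-hit$votes, hit$snp_id), , drop = FALSE]
  hit$snp_id
}

#' Pairwise tool-agreement matrix
#'
#' Phi coefficient (Pearson correlation of binary call vectors) for each tool
#' pair over the SNPs where both tools made a call. A pair with fewer than two
#' usable SNPs, or a tool with constant calls, yields \code{NA} -- flagged as
#' undefined, never coerced to 0. When both tools carry raw scores and
#' \code{use_scores} is set, Pearson correlation on scores is computed
#' instead.
#'
#' @param table a \code{vd_call_table} with >= 2 tools and >= 2 SNPs
#' @param use_scores correlate raw scores instead of binary calls
#' @return object of class \code{vd_agreement}: \code{tool_names}, symmetric
#'   matrix \code{r} with unit diagonal
#' @export
agreement_matrix <- function(table, use_scores = FALSE) {
  m <- if (use_scores) {
    if (is.null(table$scores)) vd_error("no raw scores in table",
                                        "vardyn_value_error")
    table$scores
  } else table$calls
  k <- ncol(m)
  if (k < 2L || nrow(m) < 2L) vd_error("need >= 2 tools and >= 2 SNPs",
                                       "vardyn_value_error")
  r <- diag(1, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      rij <- if (sum(ok) < 2L || stats::sd(m[ok, i]) == 0 ||
                 stats::sd(m[ok, j]) == 0) {
        NA_real_
      } else {
        stats::cor(m[ok, i], m[ok, j])
      }
      r[i, j] <- r[j, i] <- rij
    }
  }
  dimnames(r) <- list(table$tool_names, table$tool_names)
  structure(list(tool_names = table$tool_names, r = r),
            class = "vd_agreement")
}
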