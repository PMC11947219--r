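# Receptor-ligand interaction scoring between fixed sender/receiver
# populations: mean-of-means scores (subunit-wise minima for complexes),
# label-permutation significance, the 5% expressed-fraction filter, BH FDR
# within each population pair, and top-n ranking.

# Per-cell expression of a gene or complex: subunit-wise minimum.
complex_expression <- function(expr, genes) {
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) return(NULL)
  if (length(genes) == 1) return(expr[genes, ])
  do.call(pmin, lapply(genes, function(g) expr[g, ]))
}

#' Mean-of-means interaction score for one receptor-ligand pair
#'
#' score = (mean ligand expression in the sender population + mean receptor
#' expression in the receiver population) / 2. For complexes (several
#' subunits, "A_B") the per-cell expression is the subunit-wise minimum before
#' averaging. The expressed fraction is the share of cells with expression
#' strictly above zero.
#'
#' @param expr genes x cells matrix of (log-normalised) expression.
#' @param labels population label per cell.
#' @param ligand,receptor gene name or character vector of complex subunits
#'   (a single "A_B" string is split on "_").
#' @param sender,receiver population labels.
#' @return list with score, mean_ligand, mean_receptor, frac_ligand_sender,
#'   frac_receptor_receiver; NULL when a gene is missing from \code{expr}
#'   (with a message).
#' @export
interaction_score <- function(expr, labels, ligand, receptor, sender, receiver) {
  lig_genes <- unlist(strsplit(ligand, "_", fixed = TRUE))
  rec_genes <- unlist(strsplit(receptor, "_", fixed = TRUE))
  sc <- which(labels == sender); rc <- which(labels == receiver)
  if (length(sc) == 0 || length(rc) == 0)
    stop("sender/receiver population empty", call. = FALSE)
  lv <- complex_expression(expr, lig_genes)
  rv <- complex_expression(expr, rec_genes)
  if (is.null(lv) || is.null(rv)) {
    message(sprintf("pair %s -> %s skipped: gene missing from matrix",
                    paste(lig_genes, collapse = "_"),
                    paste(rec_genes, collapse = "_")))
    return(NULL)
  }
  ml <- mean(lv[sc]); mr <- mean(rv[rc])
  list(score = (ml + mr) / 2, mean_ligand = ml, mean_receptor = mr,
       frac_ligand_sender = mean(lv[sc] > 0),
       frac_receptor_receiver = mean(rv[rc] > 0))
}

#' Permutation test for receptor-ligand scores
#'
#' Population labels are shuffled across all cells and scores recomputed; the
#' one-sided (enrichment) p-value is (1 + #{perm >= obs}) / (n_perm + 1).
#' Pairs whose genes are missing are dropped with a message.
#'
#' @param expr genes x cells expression matrix.
#' @param labels population label per cell.
#' @param pairs data.frame with columns pair_id, ligand, receptor.
#' @param sender,receiver population labels for this (sender, receiver)
#'   combination.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed (bit-reproducible).
#' @return data.frame: pair_id, ligand, receptor, sender, receiver, score,
#'   frac_ligand_sender, frac_receptor_receiver, p_value.
#' @export
lr_permutation_test <- function(expr, labels, pairs, sender, receiver,
                                n_perm = 1000, seed = 1L) {
  prepped <- lapply(seq_len(nrow(pairs)), function(k) {
    lv <- complex_expression(expr, strsplit(pairs$ligand[k], "_", fixed = TRUE)[[1]])
    rv <- complex_expression(expr, strsplit(pairs$receptor[k], "_", fixed = TRUE)[[1]])
    if (is.null(lv) || is.null(rv)) {
      message(sprintf("pair %s skipped: gene missing", pairs$pair_id[k]))
      return(NULL)
    }
    list(k = k, lv = lv, rv = rv)
  })
  prepped <- Filter(Negate(is.null), prepped)
  if (length(prepped) == 0)
    return(data.frame(pair_id = character(), ligand = character(),
                      receptor = character(), sender = character(),
                      receiver = character(), score = numeric(),
                      frac_ligand_sender = numeric(),
                      frac_receptor_receiver = numeric(), p_value = numeric()))
  sc <- labels == sender; rc <- labels == receiver
  L <- do.call(rbind, lapply(prepped, `[[`, "lv"))
  Rm <- do.call(rbind, lapply(prepped, `[[`, "rv"))
  obs <- (rowMeans(L[, sc, drop = FALSE]) + rowMeans(Rm[, rc, drop = FALSE])) / 2
  ge <- rep(0L, length(obs))
  with_seed(substream_seed(seed, paste0("lrperm:", sender, ":", receiver)), {
    n <- length(labels)
    for (p in seq_len(n_perm)) {
      idx <- sample.int(n)
      ps <- sc[idx]; pr <- rc[idx]
      sperm <- (rowMeans(L[, ps, drop = FALSE]) +
                rowMeans(Rm[, pr, drop = FALSE])) / 2
      ge <- ge + (sperm >= obs)
    }
  })
  ks <- vapply(prepped, `[[`, 0L, "k")
  data.frame(pair_id = pairs$pair_id[ks], ligand = pairs$ligand[ks],
             receptor = pairs$receptor[ks], sender = sender,
             receiver = receiver, score = unname(obs),
             frac_ligand_sender = rowMeans(L[, sc, drop = FALSE] > 0),
             frac_receptor_receiver = rowMeans(Rm[, rc, drop = FALSE] > 0),
             p_value = (1 + ge) / (n_perm + 1), stringsAsFactors = FALSE)
}

#' Filter, adjust and rank receptor-ligand results
#'
#' Applies the expressed-fraction rule (by default the ligand must be
#' expressed in at least \code{min_frac} of sender cells AND the receptor in
#' at least \code{min_frac} of receiver cells; \code{frac_rule = "or"} is the
#' lenient reading), BH-adjusts p-values within each (sender, receiver)
#' combination, keeps q < alpha, and retains the \code{top_n} strongest scores
#' per combination. When \code{lymphocyte} is given, each row is labelled
#' "sender" (the lymphocyte expresses the ligand) or "receiver" (the
#' lymphocyte expresses the receptor).
#'
#' @param results row-bound \code{\link{lr_permutation_test}} output.
#' @param min_frac expressed-fraction threshold (default 0.05).
#' @param top_n interactions kept per (sender, receiver) pair (default 20).
#' @param alpha q-value threshold (default 0.05).
#' @param frac_rule "and" (default) or "or".
#' @param lymphocyte optional label of the lymphocyte population.
#' @return filtered data.frame with added q_value (and direction), ranked by
#'   score within each (sender, receiver) combination.
#' @export
filter_and_rank <- function(results, min_frac = 0.05, top_n = 20,
                            alpha = 0.05, frac_rule = c("and", "or"),
                            lymphocyte = NULL) {
  frac_rule <- match.arg(frac_rule)
  if (nrow(results) == 0) {
    results$q_value <- numeric()
    return(results)
  }
  keep <- if (frac_rule == "and")
    results$frac_ligand_sender >= min_frac &
      results$frac_receptor_receiver >= min_frac
  else
    results$frac_ligand_sender >= min_frac |
      results$frac_receptor_receiver >= min_frac
  out <- results[keep, , drop = FALSE]
  if (nrow(out) == 0) { out$q_value <- numeric(); return(out) }
  combo <- paste(out$sender, out$receiver, sep = "\r")
  out$q_value <- stats::ave(out$p_value, combo,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  out <- out[out$q_value < alpha, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  pieces <- lapply(split(out, paste(out$sender, out$receiver, sep = "\r")),
                   function(df) {
                     df <- df[order(-df$score), , drop = FALSE]
                     utils::head(df, top_n)
                   })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (!is.null(lymphocyte))
    out$direction <- ifelse(out$sender == lymphocyte, "sender", "receiver")
  out
}
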