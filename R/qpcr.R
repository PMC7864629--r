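#' Simulate a qPCR Ct table
#'
#' Generates cycle-threshold values for target and housekeeping genes in
#' two conditions ("control" and "treated"), with duplicate technical
#' replicates per assay, housekeeping Cts around a stated mean, and target
#' Cts offset by -log2(expression) so that the treated/control expression
#' ratio equals `2^true_log2_fc`.
#'
#' @param n_samples Biological samples per condition.
#' @param genes Character vector of target gene names.
#' @param housekeeping Character vector of housekeeping gene names (default
#'   GPI and GAPDH).
#' @param true_log2_fc Named (by gene) or recycled numeric vector of true
#'   log2 fold changes (treated vs control).
#' @param ct_noise_sd Per-replicate Gaussian Ct noise SD in cycles.
#' @param hk_mean_ct Mean housekeeping Ct (default 20 cycles).
#' @param target_mean_ct Mean control-condition target Ct (default 25).
#' @param n_replicates Technical replicates per assay (default 2,
#'   duplicates).
#' @param seed Integer seed.
#' @return A long-format data.frame (`sample_id`, `condition`, `gene`,
#'   `replicate`, `ct`) of class `ct_table`.
#' @export
simulate_qpcr <- function(n_samples = 3, genes = c("KCNQ2", "KCNQ3"),
                          housekeeping = c("GPI", "GAPDH"),
                          true_log2_fc = 0, ct_noise_sd = 0.2,
                          hk_mean_ct = 20, target_mean_ct = 25,
                          n_replicates = 2, seed = 1) {
  set.seed(seed)
  fc <- rep_len(true_log2_fc, length(genes))
  names(fc) <- genes
  rows <- list()
  for (cond in c("control", "treated")) {
    for (s in seq_len(n_samples)) {
      sample_id <- sprintf("%s_%d", cond, s)
      for (g in c(housekeeping, genes)) {
        base <- if (g %in% housekeeping) hk_mean_ct else {
          target_mean_ct - if (cond == "treated") fc[[g]] else 0
        }
        ct <- base + stats::rnorm(n_replicates, sd = ct_noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sample_id, condition = cond, gene = g,
          replicate = seq_len(n_replicates), ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Relative expression by the two-housekeeping-gene delta-Ct scheme
#'
#' Technical replicates are averaged on the Ct scale; the averaged Ct of
#' the two housekeeping genes is subtracted from each target gene's
#' averaged Ct to give delta-Ct, and relative expression is 2^(-delta-Ct).
#'
#' @param ct_table Long-format data.frame with columns `sample_id`, `gene`,
#'   `ct` (and optionally `replicate`, `condition`).
#' @param housekeeping The housekeeping gene pair (default GPI and GAPDH);
#'   every sample must carry all of them.
#' @return Data.frame of class `expression_table` (`sample_id`, `gene`,
#'   `delta_ct`, `rel_expr`), target genes only, plus any `condition`
#'   column carried through.
#' @export
delta_ct <- function(ct_table, housekeeping = c("GPI", "GAPDH")) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be > 0")
  agg <- stats::aggregate(ct ~ sample_id + gene, data = ct_table, FUN = mean)
  cond <- NULL
  if ("condition" %in% names(ct_table)) {
    cond <- unique(ct_table[, c("sample_id", "condition")])
  }
  rows <- lapply(split(agg, agg$sample_id), function(d) {
    hk <- d$ct[match(housekeeping, d$gene)]
    if (anyNA(hk)) {
      stop("sample ", d$sample_id[1], ": missing housekeeping gene(s) ",
           paste(housekeeping[is.na(hk)], collapse = ", "))
    }
    targets <- d[!(d$gene %in% housekeeping), , drop = FALSE]
    data.frame(sample_id = targets$sample_id, gene = targets$gene,
               delta_ct = targets$ct - mean(hk),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rel_expr <- 2^(-out$delta_ct)
  if (!is.null(cond)) {
    out$condition <- cond$condition[match(out$sample_id, cond$sample_id)]
  }
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Scale relative expression to a reference sample
#'
#' Divides each gene's relative expression by the same gene's value in the
#' reference sample, so the reference rows become exactly 1. With a `batch`
#' column the normalisation is applied within each batch (each batch must
#' contain the reference), removing between-batch scale differences.
#'
#' @param expr An `expression_table` from [delta_ct()].
#' @param reference_sample Sample id of the reference.
#' @param batch Optional name of a batch column in `expr`.
#' @return The table with an added `rel_to_reference` column.
#' @export
normalize_to_reference <- function(expr, reference_sample, batch = NULL) {
  stopifnot(all(c("sample_id", "gene", "rel_expr") %in% names(expr)))
  norm_one <- function(d) {
    ref <- d[d$sample_id == reference_sample, c("gene", "rel_expr")]
    if (nrow(ref) == 0) {
      stop("reference sample '", reference_sample, "' not found")
    }
    r <- ref$rel_expr[match(d$gene, ref$gene)]
    if (anyNA(r)) {
      stop("reference lacks gene(s): ",
           paste(unique(d$gene[is.na(r)]), collapse = ", "))
    }
    if (any(r == 0)) stop("reference relative expression is zero")
    d$rel_to_reference <- d$rel_expr / r
    d
  }
  out <- if (is.null(batch)) norm_one(expr) else {
    do.call(rbind, lapply(split(expr, expr[[batch]]), norm_one))
  }
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  out
}
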