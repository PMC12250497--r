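# Differential methylation testing over constructed technical-replicate
# designs, and the consistency / false-positive audit: consistency pairs
# compare two independent tests of the same two subjects (any disagreement
# is technical), null designs balance subject composition across the groups
# so that every significant probe is a false positive.

#' Construct an audit design
#'
#' @param id short design identifier.
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @param kind `"consistency_pair"` or `"null"`; null designs must have
#'   identical subject composition in both groups (checked against the sheet
#'   in [run_audit()]).
#' @param note free-text layout note (e.g. same-array vs across-array).
#' @return A list of class `audit_design`.
#' @export
audit_design <- function(id, group_a, group_b, kind = c("consistency_pair", "null"),
                         note = "") {
  kind <- match.arg(kind)
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  structure(list(id = id, group_a = group_a, group_b = group_b,
                 kind = kind, note = note),
            class = "audit_design")
}

#' Two-group differential methylation test per probe
#'
#' Pooled-variance two-sample t-test per probe (the linear-model form that
#' two-group array DM testers reduce to); Welch's correction is available
#' behind a flag. Probes with zero pooled variance get `p = NA` and are
#' flagged rather than assigned an extreme p-value.
#'
#' @param x probes-by-samples matrix (complete).
#' @param group_a,group_b sample ids of the two groups (>= 2 each).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame with probe_id, statistic, p.
#' @export
dmp_test <- function(x, group_a, group_b, var_equal = TRUE) {
  miss <- setdiff(c(group_a, group_b), colnames(x))
  if (length(miss)) stop("samples missing from matrix: ", paste(miss, collapse = ", "))
  a <- x[, group_a, drop = FALSE]
  b <- x[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 samples")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(x))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  stat <- (ma - mb) / se
  zero <- se == 0
  stat[zero & ma == mb] <- 0
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  p[zero] <- NA
  stat[zero] <- NA
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  data.frame(probe_id = ids, statistic = stat, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, monotone in the input and `<= 1`.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Run a differential-methylation audit
#'
#' For each design: tests group A vs group B per probe, excludes
#' zero-variance probes from the BH family (counting them), and counts
#' BH-significant probes at `alpha`. For null designs the count is the
#' false-positive tally. Consecutive `consistency_pair` designs are paired
#' and their significant sets compared by overlap and Jaccard index.
#'
#' @param x probes-by-samples matrix (complete).
#' @param sheet a [sample_sheet].
#' @param designs list of [audit_design] objects.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return List of class `audit_report`: `table` (per design: n_tested,
#'   n_zero_variance, n_significant, kind), `pairs` (overlap/Jaccard per
#'   consistency pair), `significant` (named list of probe-id sets).
#' @export
run_audit <- function(x, sheet, designs, alpha = 0.05) {
  sheet <- validate_sample_sheet(sheet)
  if (inherits(designs, "audit_design")) designs <- list(designs)
  sig_sets <- list()
  rows <- list()
  for (d in designs) {
    miss <- setdiff(c(d$group_a, d$group_b), sheet$sample_id)
    if (length(miss)) {
      stop("design '", d$id, "' references unknown sample(s): ",
           paste(miss, collapse = ", "))
    }
    if (d$kind == "null") {
      sa <- sort(sheet$subject[match(d$group_a, sheet$sample_id)])
      sb <- sort(sheet$subject[match(d$group_b, sheet$sample_id)])
      if (!identical(sa, sb)) {
        stop("null design '", d$id, "' has unequal subject composition")
      }
    }
    res <- dmp_test(x, d$group_a, d$group_b)
    zero <- is.na(res$p)
    adj <- bh_adjust(res$p[!zero])
    sig <- res$probe_id[!zero][adj < alpha]
    sig_sets[[d$id]] <- sig
    rows[[length(rows) + 1]] <- data.frame(
      id = d$id, kind = d$kind, n_tested = sum(!zero),
      n_zero_variance = sum(zero), n_significant = length(sig),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  pair_ids <- tab$id[tab$kind == "consistency_pair"]
  pairs <- NULL
  if (length(pair_ids) >= 2) {
    prs <- list()
    for (k in seq(1, length(pair_ids) - 1, by = 2)) {
      s1 <- sig_sets[[pair_ids[k]]]
      s2 <- sig_sets[[pair_ids[k + 1]]]
      ov <- length(intersect(s1, s2))
      un <- length(union(s1, s2))
      prs[[length(prs) + 1]] <- data.frame(
        id1 = pair_ids[k], id2 = pair_ids[k + 1], overlap = ov,
        jaccard = if (un == 0) NA_real_ else ov / un, stringsAsFactors = FALSE
      )
    }
    pairs <- do.call(rbind, prs)
  }
  structure(list(table = tab, pairs = pairs, significant = sig_sets,
                 alpha = alpha),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report> alpha =", x$alpha, "\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$pairs)) {
    cat("consistency pairs:\n")
    print(x$pairs, row.names = FALSE)
  }
  invisible(x)
}

#' Build the canonical audit designs from a replicate-plate layout
#'
#' From a sheet produced by [emulate_paper_layout()] (4 subjects, 8 pooled +
#' 8 independent), constructs:
#' \describe{
#'   \item{group1_across_array}{subjects B vs D, four pooled replicates
#'     each, every replicate on a different slide;}
#'   \item{group2_same_array}{subjects B vs D, four pooled replicates each,
#'     all eight sharing one slide;}
#'   \item{null_position}{a position-confounded null: both groups contain
#'     two pooled replicates of B and two of D, but group A sits in low
#'     chamber numbers (2-3) and group B in high ones (7-8), so the
#'     underlying biology is identical across groups and any significant
#'     probe is a positional false positive;}
#'   \item{null_within_subject}{a global-null split of one subject's eight
#'     pooled replicates into two groups of four.}
#' }
#'
#' @param sheet a [sample_sheet] from the canonical layout.
#' @return Named list of [audit_design] objects.
#' @export
build_paper_designs <- function(sheet) {
  sheet <- validate_sample_sheet(sheet)
  subs <- sort(unique(sheet$subject))
  if (length(subs) < 4) stop("canonical designs need 4 subjects")
  sB <- subs[2]; sD <- subs[4]
  pooled <- sheet[sheet$pooled, , drop = FALSE]

  # the slide carrying 4 pooled replicates of both focus subjects
  tab <- table(pooled$slide, pooled$subject)
  shared <- rownames(tab)[tab[, sB] >= 4 & tab[, sD] >= 4]
  if (!length(shared)) stop("layout cannot satisfy the same-array design")
  shared <- shared[1]
  on_shared <- pooled[pooled$slide == shared, , drop = FALSE]
  on_shared <- on_shared[order(on_shared$chamber), , drop = FALSE]

  pick_across <- function(s) {
    cand <- pooled[pooled$subject == s & pooled$slide != shared, , drop = FALSE]
    cand <- cand[order(cand$slide, cand$chamber), , drop = FALSE]
    cand <- cand[!duplicated(cand$slide), , drop = FALSE]
    if (nrow(cand) < 4) stop("layout cannot satisfy the across-array design")
    cand$sample_id[1:4]
  }
  g1 <- audit_design("group1_across_array",
                     pick_across(sB), pick_across(sD),
                     kind = "consistency_pair",
                     note = "B vs D, replicates on distinct slides")
  bi <- on_shared$sample_id[on_shared$subject == sB][1:4]
  di <- on_shared$sample_id[on_shared$subject == sD][1:4]
  g2 <- audit_design("group2_same_array", bi, di,
                     kind = "consistency_pair",
                     note = paste0("B vs D, all replicates on slide ", shared))
  pick_chambers <- function(chs) {
    got <- character(0)
    for (s in c(sB, sD)) {
      rows <- pooled[pooled$subject == s & pooled$chamber %in% chs, , drop = FALSE]
      rows <- rows[order(rows$chamber, rows$slide), , drop = FALSE]
      if (nrow(rows) < 2) stop("layout cannot satisfy the position-confounded null design")
      got <- c(got, rows$sample_id[1:2])
    }
    got
  }
  nul <- audit_design("null_position", pick_chambers(c(2, 3)), pick_chambers(c(7, 8)),
                      kind = "null",
                      note = "balanced B/D composition, chambers 2-3 vs 7-8")
  other <- setdiff(subs, c(sB, sD))[1]
  po <- sheet[sheet$pooled & sheet$subject == other, , drop = FALSE]
  po <- po[order(po$chamber), , drop = FALSE]
  if (nrow(po) < 8) stop("layout cannot satisfy the within-subject null design")
  nw <- audit_design("null_within_subject",
                     po$sample_id[po$chamber %% 2 == 1],
                     po$sample_id[po$chamber %% 2 == 0],
                     kind = "null",
                     note = paste0("subject ", other, " pooled replicates, odd vs even chambers"))
  list(group1_across_array = g1, group2_same_array = g2,
       null_position = nul, null_within_subject = nw)
}
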