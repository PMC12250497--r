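# Generic linear epigenetic-clock application. A clock is an intercept plus
# a sparse linear combination of CpG beta values; chronological-age clocks
# trained on log-linear transformed age invert the transform after the
# linear predictor. Published coefficient sets are user-supplied files; a
# synthetic fixture clock (clearly labelled synthetic) ships for tests.

#' Define a linear epigenetic clock
#'
#' @param name clock name.
#' @param intercept linear-predictor intercept.
#' @param coefficients named numeric vector: probe id -> coefficient.
#' @param age_transform `"identity"` or `"log_linear"`; the log-linear
#'   transform is the standard piecewise map with knot `adult_age`:
#'   the linear predictor `s` decodes to `(1 + adult_age) * exp(s) - 1`
#'   when `s < 0` and `adult_age + s * (1 + adult_age)` otherwise.
#' @param adult_age knot of the log-linear transform (years; must be > 0
#'   when `age_transform = "log_linear"`).
#' @return A list of class `clock_definition`.
#' @export
clock_definition <- function(name, intercept, coefficients,
                             age_transform = c("identity", "log_linear"),
                             adult_age = 20) {
  age_transform <- match.arg(age_transform)
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients))) {
    stop("coefficients must be uniquely named by probe id")
  }
  if (age_transform == "log_linear" && adult_age <= 0) stop("adult_age must be > 0")
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, age_transform = age_transform,
                 adult_age = adult_age),
            class = "clock_definition")
}

inverse_age_transform <- function(s, clock) {
  if (clock$age_transform == "identity") return(s)
  a <- clock$adult_age
  ifelse(s < 0, (1 + a) * exp(s) - 1, a + s * (1 + a))
}

#' Read / write a clock definition
#'
#' CSV with columns `probe_id,coefficient`, preceded by comment lines
#' `#name=`, `#intercept=`, `#transform=`, `#adult_age=` carrying the
#' metadata.
#'
#' @param path CSV file path.
#' @return [read_clock()] returns a [clock_definition].
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  clock_definition(
    name = meta$name %||% "clock",
    intercept = as.numeric(meta$intercept %||% 0),
    coefficients = stats::setNames(body$coefficient, body$probe_id),
    age_transform = meta$transform %||% "identity",
    adult_age = as.numeric(meta$adult_age %||% 20)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_clock
#' @param clock a [clock_definition].
#' @export
write_clock <- function(clock, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#name=", clock$name),
    paste0("#intercept=", fmt_num(clock$intercept)),
    paste0("#transform=", clock$age_transform),
    paste0("#adult_age=", fmt_num(clock$adult_age)),
    "probe_id,coefficient",
    paste0(names(clock$coefficients), ",", fmt_num(clock$coefficients))
  ), con)
  invisible(path)
}

#' Apply a linear clock to a beta matrix
#'
#' Computes the per-sample linear predictor `intercept + sum(coef * beta)`
#' over the clock's probes and inverts the age transform. Probes present
#' but `NA` in some samples are handled per `missing_policy`; probes absent
#' from the matrix entirely count against coverage.
#'
#' @param beta probes-by-samples matrix.
#' @param clock a [clock_definition].
#' @param missing_policy `"error"` or `"mean_impute_from_cohort"` (replace a
#'   probe's missing entries by its across-sample mean).
#' @param min_coverage minimum fraction of clock probes that must be present
#'   in the matrix (default 1).
#' @return Named numeric vector of predicted ages per sample.
#' @export
apply_clock <- function(beta, clock, missing_policy = c("error", "mean_impute_from_cohort"),
                        min_coverage = 1) {
  missing_policy <- match.arg(missing_policy)
  probes <- names(clock$coefficients)
  present <- probes %in% rownames(beta)
  coverage <- mean(present)
  if (coverage < min_coverage) {
    stop("clock coverage ", signif(coverage, 3), " below ", min_coverage,
         "; missing probes: ",
         paste(utils::head(probes[!present], 10), collapse = ", "))
  }
  if (any(!present)) warning(sum(!present), " clock probe(s) absent; dropped")
  use <- probes[present]
  b <- beta[use, , drop = FALSE]
  if (anyNA(b)) {
    if (missing_policy == "error") {
      bad <- rownames(b)[rowSums(is.na(b)) > 0]
      stop("missing beta values for clock probe(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    rm_ <- rowMeans(b, na.rm = TRUE)
    idx <- which(is.na(b), arr.ind = TRUE)
    b[idx] <- rm_[idx[, 1]]
  }
  s <- clock$intercept + as.vector(crossprod(b, clock$coefficients[use]))
  stats::setNames(inverse_age_transform(s, clock), colnames(beta))
}

#' Replicate-stability report for clock CpGs
#'
#' Summarises each clock CpG's mean and range across every subject's
#' technical replicates, ranks CpGs by influence (range times absolute
#' coefficient, maximised over subjects), reports each subject's SD of
#' predicted age across replicates, and -- when low-level data are supplied
#' -- screens the flagged CpGs' mean FI and bead-level SD in each channel
#' with a single-outlier Grubbs test across samples.
#'
#' @param beta probes-by-samples matrix.
#' @param sheet a [sample_sheet]; >= 2 replicates per subject.
#' @param clock a [clock_definition].
#' @param lowlevel optional [lowlevel_set] for the Grubbs screen.
#' @param influence_threshold flag CpGs whose influence exceeds this value
#'   (default 0.05, beta-range times coefficient units).
#' @return List of class `clock_stability`: `cpg_stats` (per CpG x subject),
#'   `influence` (per CpG, sorted), `prediction_spread` (per subject),
#'   `flagged`, and `grubbs` (per flagged CpG x channel x statistic).
#' @export
clock_stability_report <- function(beta, sheet, clock, lowlevel = NULL,
                                   influence_threshold = 0.05) {
  sh <- match_sheet(beta, validate_sample_sheet(sheet))
  probes <- intersect(names(clock$coefficients), rownames(beta))
  subs <- unique(sh$subject)
  stats_rows <- list()
  infl <- stats::setNames(rep(0, length(probes)), probes)
  for (s in subs) {
    jj <- which(sh$subject == s)
    if (length(jj) < 2) stop("subject ", s, " has fewer than 2 replicates")
    bs <- beta[probes, jj, drop = FALSE]
    rng <- apply(bs, 1, function(v) diff(range(v)))
    stats_rows[[length(stats_rows) + 1]] <- data.frame(
      probe_id = probes, subject = s, mean = rowMeans(bs), range = rng,
      coefficient = clock$coefficients[probes],
      row.names = NULL, stringsAsFactors = FALSE
    )
    infl <- pmax(infl, rng * abs(clock$coefficients[probes]))
  }
  cpg_stats <- do.call(rbind, stats_rows)
  pred <- apply_clock(beta, clock, missing_policy = "mean_impute_from_cohort",
                      min_coverage = 0)
  spread <- do.call(rbind, lapply(subs, function(s) {
    jj <- which(sh$subject == s)
    data.frame(subject = s, sd_predicted_age = stats::sd(pred[jj]),
               stringsAsFactors = FALSE)
  }))
  infl <- sort(infl, decreasing = TRUE)
  flagged <- names(infl)[infl > influence_threshold]
  grubbs <- NULL
  if (!is.null(lowlevel) && length(flagged)) {
    rows <- list()
    for (pid in flagged) {
      for (ch in c("green", "red")) {
        for (stat in c("mean_fi", "sd_fi")) {
          v <- lowlevel[[stat]][[ch]][pid, ]
          gt <- tryCatch(grubbs_test(v), error = function(e) NULL)
          if (is.null(gt)) next
          rows[[length(rows) + 1]] <- data.frame(
            probe_id = pid, channel = ch, statistic = stat, G = gt$statistic,
            p = gt$p.value, outlier_sample = lowlevel$samples[gt$outlier],
            n_beads = lowlevel$n_beads[[ch]][pid, gt$outlier],
            stringsAsFactors = FALSE
          )
        }
      }
    }
    grubbs <- do.call(rbind, rows)
  }
  structure(list(cpg_stats = cpg_stats, influence = infl,
                 prediction_spread = spread, flagged = flagged,
                 grubbs = grubbs),
            class = "clock_stability")
}

#' A synthetic fixture clock
#'
#' Builds a deterministic 30-CpG synthetic clock over the given probe ids:
#' a fixed heavy-tailed coefficient profile (a few dominant CpGs, many small
#' ones, alternating sign) with a log-linear age transform. This is a test
#' fixture, not a published clock.
#'
#' @param probe_ids character vector of >= 30 probe ids; the first 30 are
#'   used.
#' @return A [clock_definition] named `"synthetic30"`.
#' @export
synthetic_clock <- function(probe_ids) {
  if (length(probe_ids) < 30) stop("need at least 30 probe ids")
  magnitudes <- c(6.0, 2.4, 2.1, 1.8, 1.6, 1.4, 1.25, 1.1, 1.0, 0.9,
                  0.8, 0.72, 0.65, 0.58, 0.52, 0.47, 0.42, 0.38, 0.34, 0.30,
                  0.27, 0.24, 0.21, 0.19, 0.17, 0.15, 0.13, 0.11, 0.10, 0.08) / 10
  signs <- rep(c(1, -1), 15)
  clock_definition(
    name = "synthetic30",
    intercept = 0.6,
    coefficients = stats::setNames(magnitudes * signs, probe_ids[1:30]),
    age_transform = "log_linear",
    adult_age = 20
  )
}
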