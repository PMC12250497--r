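# Tabular readers/writers. Dialects:
#   sample sheet  CSV  sample_id,subject,slide,chamber,pooled
#   manifest      TSV  probe_id,probe_type,design_channel
#   matrices      TSV  probes x samples, first column probe_id, "NA" missing
#   low-level set one TSV per channel, long format
#                 probe_id,sample_id,mean_fi,sd_fi,n_beads,oob
# Numeric values are written with "%.17g" so that write -> read round-trips
# doubles bit-identically.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read / write a sample sheet
#'
#' @param path CSV file path.
#' @return [read_sample_sheet()] returns a validated [sample_sheet].
#' @export
read_sample_sheet <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_sheet(x$sample_id, x$subject, x$slide, x$chamber, x$pooled)
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet].
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a probe manifest
#'
#' @param path TSV file path.
#' @return [read_manifest()] returns a validated [probe_manifest].
#' @export
read_manifest <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe_manifest(x$probe_id, x$probe_type, x$design_channel)
}

#' @rdname read_manifest
#' @param manifest a [probe_manifest].
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a probes-by-samples matrix as TSV
#'
#' @param path TSV file path.
#' @return [read_matrix_tsv()] returns a numeric matrix with probe rownames.
#' @export
read_matrix_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param x numeric matrix (probes x samples).
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.matrix(x))
  body <- matrix(ifelse(is.na(x), "NA", fmt_num(x)), nrow = nrow(x))
  df <- data.frame(probe_id = rownames(x), body, stringsAsFactors = FALSE)
  names(df) <- c("probe_id", colnames(x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a low-level array set
#'
#' Writes `green.tsv` and `red.tsv` (long format, one row per probe, sample
#' and channel, with an `oob` flag for out-of-band rows) into `dir`.
#'
#' @param dir directory holding `green.tsv` and `red.tsv`.
#' @param manifest a [probe_manifest] defining probe order and types.
#' @return [read_lowlevel()] returns a [lowlevel_set].
#' @export
read_lowlevel <- function(dir, manifest) {
  manifest <- validate_manifest(manifest)
  read_ch <- function(ch) {
    x <- utils::read.delim(file.path(dir, paste0(ch, ".tsv")), stringsAsFactors = FALSE)
    samples <- unique(x$sample_id)
    shape <- function(col) {
      m <- matrix(NA_real_, nrow(manifest), length(samples),
                  dimnames = list(manifest$probe_id, samples))
      m[cbind(match(x$probe_id, manifest$probe_id), match(x$sample_id, samples))] <- x[[col]]
      if (anyNA(m)) stop("incomplete ", ch, " channel table")
      m
    }
    oob_flag <- ifelse(oob_channel(manifest) == ch, TRUE, FALSE)
    oob_flag[is.na(oob_flag)] <- FALSE
    got <- x$oob[match(manifest$probe_id, x$probe_id)]
    if (!identical(as.logical(got), as.logical(oob_flag))) {
      stop("oob flags in ", ch, ".tsv disagree with the manifest")
    }
    beads <- round(shape("n_beads"))
    storage.mode(beads) <- "integer"
    list(mean = shape("mean_fi"), sd = shape("sd_fi"), beads = beads)
  }
  g <- read_ch("green"); r <- read_ch("red")
  lowlevel_set(
    mean_fi = list(green = g$mean, red = r$mean),
    sd_fi = list(green = g$sd, red = r$sd),
    n_beads = list(green = g$beads, red = r$beads),
    manifest = manifest
  )
}

#' @rdname read_lowlevel
#' @param lowlevel a [lowlevel_set].
#' @export
write_lowlevel <- function(lowlevel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- lowlevel$manifest
  for (ch in c("green", "red")) {
    oob_flag <- ifelse(is.na(oob_channel(man)), FALSE, oob_channel(man) == ch)
    df <- data.frame(
      probe_id = rep(man$probe_id, times = length(lowlevel$samples)),
      sample_id = rep(lowlevel$samples, each = nrow(man)),
      mean_fi = fmt_num(as.vector(lowlevel$mean_fi[[ch]])),
      sd_fi = fmt_num(as.vector(lowlevel$sd_fi[[ch]])),
      n_beads = as.vector(lowlevel$n_beads[[ch]]),
      oob = rep(oob_flag, times = length(lowlevel$samples)),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, file.path(dir, paste0(ch, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
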