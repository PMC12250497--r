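#' Construct and validate a sample sheet
#'
#' A sample sheet maps each assay to its subject, physical slide (Sentrix
#' barcode), chamber number (Sentrix position, 1-8 on a one-column layout
#' R01C01..R08C01), and whether the replicate came from the subject's pooled
#' DNA sample or was independently prepared.
#'
#' @param sample_id character, unique assay identifiers.
#' @param subject character, biological subject of each assay.
#' @param slide character, Sentrix-barcode-like slide identifier.
#' @param chamber integer in 1..8, chamber number within the slide.
#' @param pooled logical, `TRUE` for aliquots of the subject's pooled sample.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, subject, slide, chamber, pooled) {
  x <- data.frame(
    sample_id = as.character(sample_id),
    subject = as.character(subject),
    slide = as.character(slide),
    chamber = as.integer(chamber),
    pooled = as.logical(pooled),
    stringsAsFactors = FALSE
  )
  class(x) <- c("sample_sheet", "data.frame")
  validate_sample_sheet(x)
}

#' @rdname sample_sheet
#' @param x object to validate.
#' @export
validate_sample_sheet <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("sample_id", "subject", "slide", "chamber", "pooled")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  dup <- duplicated(x$sample_id)
  if (any(dup)) {
    stop("duplicate sample_id in row(s) ", paste(which(dup), collapse = ", "),
         ": ", paste(unique(x$sample_id[dup]), collapse = ", "))
  }
  bad <- which(!(x$chamber %in% 1:8) | is.na(x$chamber))
  if (length(bad)) {
    stop("chamber out of range 1-8 in row(s) ", paste(bad, collapse = ", "),
         " (sample ", paste(x$sample_id[bad], collapse = ", "), ")")
  }
  if (anyNA(x$pooled)) stop("pooled flag must be TRUE/FALSE")
  cell <- paste(x$slide, x$chamber)
  dup <- duplicated(cell)
  if (any(dup)) {
    stop("(slide, chamber) cell occupied more than once in row(s) ",
         paste(which(dup), collapse = ", "))
  }
  if (!inherits(x, "sample_sheet")) class(x) <- c("sample_sheet", "data.frame")
  x
}

#' Construct and validate a probe manifest
#'
#' The manifest records each probe's Infinium design: Type II probes read the
#' methylated signal in the green channel and the unmethylated signal in the
#' red channel on a single bead type (`design_channel = "both"`); Type I
#' probes read both alleles in one design channel, and their signal in the
#' opposite channel is the out-of-band (OOB) background read.
#'
#' @param probe_id character, unique probe identifiers.
#' @param probe_type `"I"` or `"II"`.
#' @param design_channel `"green"` or `"red"` for Type I probes, `"both"` for
#'   Type II probes.
#' @return A `data.frame` of class `probe_manifest`.
#' @export
probe_manifest <- function(probe_id, probe_type, design_channel) {
  x <- data.frame(
    probe_id = as.character(probe_id),
    probe_type = as.character(probe_type),
    design_channel = as.character(design_channel),
    stringsAsFactors = FALSE
  )
  class(x) <- c("probe_manifest", "data.frame")
  validate_manifest(x)
}

#' @rdname probe_manifest
#' @param x object to validate.
#' @export
validate_manifest <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("probe_id", "probe_type", "design_channel")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  dup <- duplicated(x$probe_id)
  if (any(dup)) stop("duplicate probe_id in row(s) ", paste(which(dup), collapse = ", "))
  bad <- which(!(x$probe_type %in% c("I", "II")))
  if (length(bad)) stop("probe_type must be 'I' or 'II' (row ", paste(bad, collapse = ", "), ")")
  bad <- which(x$probe_type == "II" & x$design_channel != "both")
  if (length(bad)) {
    stop("Type II probes must have design_channel 'both' (row ",
         paste(bad, collapse = ", "), ")")
  }
  bad <- which(x$probe_type == "I" & !(x$design_channel %in% c("green", "red")))
  if (length(bad)) {
    stop("Type I probes must have design_channel 'green' or 'red' (row ",
         paste(bad, collapse = ", "), ")")
  }
  if (!inherits(x, "probe_manifest")) class(x) <- c("probe_manifest", "data.frame")
  x
}

#' Low-level array summaries for a set of samples
#'
#' Holds, per probe, sample and colour channel, the across-bead mean
#' fluorescence intensity, the across-bead standard deviation, and the bead
#' count -- the information carried by idat files. Values are stored as
#' probes-by-samples matrices per channel. Probe-level aggregate convention:
#' a Type II probe's green entry is its methylated signal and its red entry
#' the unmethylated signal; a Type I probe's design-channel entry is the
#' two-bead-type in-band total and its opposite-channel entry is the
#' out-of-band background total.
#'
#' @param mean_fi,sd_fi,n_beads named lists with `green` and `red`
#'   probes-by-samples matrices (rownames = probe ids, colnames = sample ids).
#' @param manifest a [probe_manifest].
#' @return An object of class `lowlevel_set`.
#' @export
lowlevel_set <- function(mean_fi, sd_fi, n_beads, manifest) {
  manifest <- validate_manifest(manifest)
  for (nm in c("green", "red")) {
    for (part in list(mean_fi, sd_fi, n_beads)) {
      if (!is.matrix(part[[nm]])) stop("channel '", nm, "' must be a matrix")
    }
    if (!identical(rownames(mean_fi[[nm]]), manifest$probe_id)) {
      stop("rownames of mean_fi$", nm, " must equal manifest$probe_id")
    }
  }
  x <- structure(
    list(mean_fi = mean_fi, sd_fi = sd_fi, n_beads = n_beads,
         manifest = manifest, samples = colnames(mean_fi$green)),
    class = "lowlevel_set"
  )
  validate_lowlevel(x)
}

#' @rdname lowlevel_set
#' @param x object to validate.
#' @export
validate_lowlevel <- function(x) {
  stopifnot(inherits(x, "lowlevel_set"))
  for (nm in c("green", "red")) {
    m <- x$mean_fi[[nm]]; s <- x$sd_fi[[nm]]; b <- x$n_beads[[nm]]
    if (any(!is.finite(m)) || any(m < 0)) stop("mean_fi (", nm, ") must be finite and >= 0")
    if (any(!is.finite(s)) || any(s < 0)) stop("sd_fi (", nm, ") must be finite and >= 0")
    if (any(b < 0) || any(b != round(b))) stop("n_beads (", nm, ") must be non-negative integers")
    if (any(s[b <= 1] != 0)) stop("sd_fi must be 0 wherever n_beads <= 1 (", nm, ")")
  }
  x
}

#' Which channel holds a probe's out-of-band read
#'
#' @param manifest a [probe_manifest].
#' @return Character vector per probe: `"green"`, `"red"`, or `NA` for Type II
#'   probes (which have no out-of-band read).
#' @export
oob_channel <- function(manifest) {
  ifelse(manifest$probe_type == "I",
         ifelse(manifest$design_channel == "red", "green", "red"),
         NA_character_)
}

#' @export
print.lowlevel_set <- function(x, ...) {
  cat("<lowlevel_set> ", nrow(x$manifest), " probes x ", length(x$samples),
      " samples (", sum(x$manifest$probe_type == "II"), " Type II, ",
      sum(x$manifest$probe_type == "I"), " Type I)\n", sep = "")
  invisible(x)
}

# ids of Type II probes (the probes entering channel-wise and beta analyses)
type2_probes <- function(manifest) manifest$probe_id[manifest$probe_type == "II"]
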