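# Shared fixtures, built in code.

# minimal valid sheet: S subjects x k replicates laid over slides of 8
tiny_sheet <- function(S = 2, k = 4) {
  n <- S * k
  slides <- sprintf("SL%02d", (seq_len(n) - 1) %/% 8 + 1)
  sample_sheet(
    sample_id = sprintf("s%02d", seq_len(n)),
    subject = rep(LETTERS[seq_len(S)], each = k),
    slide = slides,
    chamber = (seq_len(n) - 1) %% 8 + 1,
    pooled = TRUE
  )
}

# hand-built lowlevel_set from explicit channel matrices
mk_lowlevel <- function(green, red, manifest, n_beads = 10L) {
  zer <- matrix(0, nrow(green), ncol(green), dimnames = dimnames(green))
  nb <- matrix(as.integer(n_beads), nrow(green), ncol(green), dimnames = dimnames(green))
  lowlevel_set(
    mean_fi = list(green = green, red = red),
    sd_fi = list(green = zer, red = zer),
    n_beads = list(green = nb, red = nb),
    manifest = manifest
  )
}

# manifest of n Type II probes followed by k1 Type I probes
mk_manifest <- function(n2, k1 = 0) {
  n <- n2 + k1
  probe_manifest(
    sprintf("cg%06d", seq_len(n)),
    c(rep("II", n2), rep("I", k1)),
    c(rep("both", n2), rep(c("green", "red"), length.out = k1))
  )
}
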