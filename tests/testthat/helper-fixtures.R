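# shared fixtures: small, fast phantoms for extraction tests

# a reduced-grid phantom spec per subtype (same class contrasts as the
# defaults, smaller grid and lesion so the full catalog extracts in
# milliseconds per subject)
tiny_phantom_specs <- function() {
  lapply(default_phantom_specs(), function(sp) {
    sp$grid_shape <- c(24L, 24L, 24L)
    sp$semi_axes <- c(6, 5, 4)
    sp
  })
}

tiny_cohort <- function(n_per_class = c(LuminalA = 1L, LuminalB = 1L,
                                        HER2pos = 0L, TN = 0L), seed = 11L) {
  generate_image_cohort(cohort_spec(n_per_class, tiny_phantom_specs(), seed))
}

# direct construction of a well-formed subject from arrays
toy_subject <- function(id = "T1", label = "TN", n = 8L, seed = 1L) {
  set.seed(seed)
  mk <- function(tag) image_volume(array(stats::rnorm(n^3, 100, 10), rep(n, 3)),
                                   axis_label = tag)
  mask <- array(FALSE, rep(n, 3))
  mask[3:6, 3:6, 3:6] <- TRUE
  m <- tumor_mask(mask)
  mr_subject(id,
             image_series(lapply(paste0("DCE_phase", 0:5), mk), "DCE_time", 0:5),
             image_series(lapply(c("DWI_b50", "DWI_b400", "DWI_b800"), mk),
                          "DWI_bvalue", c(50, 400, 800)),
             m, m, label)
}

# small labelled feature table built directly from a matrix
toy_table <- function(X, labels, prefix = "f") {
  meta <- data.frame(name = sprintf("%s%03d", prefix, seq_len(ncol(X))),
                     group = "noise", source = "synthetic",
                     base_feature = "", statistic = "",
                     stringsAsFactors = FALSE)
  feature_table(X, sprintf("S%03d", seq_len(nrow(X))), labels, meta)
}
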