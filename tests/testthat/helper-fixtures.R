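# Small deterministic fixtures shared across test files.

tiny_volume <- function(values, spacing = c(1, 1, 1)) {
  suv_volume(array(values, dim = if (is.null(dim(values)))
    c(length(values), 1L, 1L) else dim(values)), spacing)
}

full_mask_like <- function(volume) {
  roi_mask(array(1L, dim(volume$values)), volume$spacing_mm)
}

# 12 x 3 two-way layout with frozen ICC(A,1) oracle values computed with
# an independent reference implementation (pingouin 0.6.1):
# ICC = 0.7607599029, CI = (0.3187560060, 0.9273310812).
icc_fixture_matrix <- function() {
  matrix(c(
    5.3377324285, 6.2683376832, 5.2384717509,
    3.5303696623, 4.5443912858, 3.1805745933,
    6.1896763465, 6.1254882403, 5.3580200140,
    5.6000999442, 6.9518353857, 5.5632999754,
    2.8348009003, 3.2728980361, 3.0151194041,
    3.8805425253, 4.3041867989, 3.6132309946,
    6.1986642036, 5.3246328950, 4.5717190386,
    4.2768710435, 5.3917471189, 4.9482435540,
    4.9262251137, 4.9631206040, 4.2709582347,
    4.4722524663, 4.9185831580, 4.1185332066,
    5.5466431212, 6.3954786364, 5.6377408794,
    5.8871362338, 6.6135063244, 5.5895897098), ncol = 3, byrow = TRUE)
}

# Feature table builder for agreement tests: values[[variant]] is a
# per-case numeric vector.
toy_feature_table <- function(values, parameter = "SM", feature = "f1",
                              cases = NULL) {
  col <- switch(parameter, SM = "segmentation", GL = "gray_level",
                RA = "recon")
  rows <- list()
  for (lab in names(values)) {
    v <- values[[lab]]
    ids <- cases %||% paste0("c", seq_along(v))
    base <- data.frame(case_id = ids, segmentation = "MTV1",
                       gray_level = 64L, recon = "OSEM",
                       feature = feature, value = v,
                       stringsAsFactors = FALSE)
    base[[col]] <- if (col == "gray_level") as.integer(lab) else lab
    rows[[length(rows) + 1L]] <- base
  }
  validate_feature_table(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
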