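# Small-scale fixtures built in code: a reduced atlas and a reduced
# synthetic spec keep the multivariate fits fast while preserving the
# full statistical structure (4 sites, correlated DAS, per-group TICV,
# exchangeable parcel noise, plantable interaction).

tinyAtlas <- function(p = 12) {
  half <- ceiling(p / 2)
  labels <- c(sprintf("lh.P%02d", seq_len(half)),
              sprintf("rh.P%02d", seq_len(p - half)))
  ParcelAtlas(labels = labels, hemisphere = sub("\\..*$", "", labels))
}

tinySpec <- function(p = 12, n_case = 30, n_ctrl = 26, delta = 0,
                     n_targets = 4, metrics = c(area = 25, CD = 10), ...) {
  atlas <- tinyAtlas(p)
  syntheticSpec(n_case = n_case, n_case_female = floor(n_case / 2),
                n_ctrl = n_ctrl, n_ctrl_female = floor(n_ctrl / 2),
                baseline = metrics, delta = delta,
                target_parcels = parcelLabels(atlas)[seq_len(n_targets)],
                atlas = atlas, ...)
}

# hand-built minimal cohort, balanced 2x2, for exact-value tests
handCohort <- function(n_per_cell = 3, ticv = NULL) {
  n <- 4 * n_per_cell
  sex <- rep(c(1, -1), each = 2 * n_per_cell)
  dx <- rep(c(1, -1, 1, -1), each = n_per_cell)
  set.seed(n)
  data.frame(subject_id = sprintf("H%03d", seq_len(n)),
             site = rep(paste0("site", 1:2), length.out = n),
             sex = sex, diagnosis = dx,
             age = seq(8, 17, length.out = n),
             das_v = rnorm(n, 100, 10), das_nv = rnorm(n, 100, 10),
             das_s = rnorm(n, 100, 10), das_gca = rnorm(n, 100, 10),
             das_snc = rnorm(n, 100, 10),
             ticv = if (is.null(ticv)) rnorm(n, 215, 20) else rep(ticv, n))
}
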