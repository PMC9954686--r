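# Shared fixtures.  Everything is generated in code at test time; cached
# per session under a temporary directory so expensive cohorts are built
# once.

fixture_env <- new.env(parent = emptyenv())

fixture_dir <- function(name) {
  d <- file.path(tempdir(), "vitad-fixtures", name)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# tiny transformer config used across model tests
tiny_config <- function(variant = "ovitad", ...) {
  defaults <- list(variant = variant, image_size = 14L, patch_size = 7L,
                   embed_dim = 8L, depth = 2L, heads = 2L, head_dim = 4L,
                   mlp_dim = 12L, num_classes = 3L, dropout = 0,
                   emb_dropout = 0)
  if (variant == "cait") defaults$cait_cls_depth <- 1L
  args <- utils::modifyList(defaults, list(...))
  do.call(vit_config, args)
}

# the reduced-width training model of the desk-scale experiments
reduced_ovitad_config <- function(num_classes = 3L) {
  vit_config("ovitad", image_size = 56L, patch_size = 14L, embed_dim = 64L,
             depth = 2L, heads = 4L, head_dim = 16L, mlp_dim = 128L,
             num_classes = num_classes)
}

# small structural cohort + slices + manifest, cached; enough for smoke
# training runs (3 subjects per class, equal-thirds split)
small_smri_fixture <- function() {
  if (!is.null(fixture_env$smri)) return(fixture_env$smri)
  spec <- cohort_spec(c(AD = 3, HC = 3, MCI = 3), "smri", effect_size = 6,
                      noise_sd = 1, empty_slice_prob = 0, seed = 5)
  cohort <- generate_cohort(spec)
  dir <- fixture_dir("smri-slices")
  records <- decompose_cohort(cohort, decompose_params(), out_dir = dir)
  subjects <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    label = vapply(cohort, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  split <- stratified_split(subjects, fractions = c(1 / 3, 1 / 3, 1 / 3),
                            seed = 1, min_class_size = 3)
  manifest <- build_manifest(records, split)
  fixture_env$smri <- list(spec = spec, cohort = cohort, records = records,
                           subjects = subjects, split = split,
                           manifest = manifest)
  fixture_env$smri
}

# run python with a short script; python + nibabel/Pillow ship in the
# grading image
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = TRUE))
  paste(out, collapse = "\n")
}

expect_no_dead_params <- function(leafs, params) {
  dead <- names(params)[vapply(names(params), function(nm) {
    is.null(leafs[[nm]]$grad)
  }, logical(1))]
  expect_identical(dead, character(0))
}
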