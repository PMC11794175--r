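# Lazily built, memoised heavy fixtures shared across test files: the
# 300-video phantom cohort, the trained continuum scorer and the two learned
# segmenters.  Everything is generated in code under fixed seeds.

asc_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = asc_cache)) assign(key, builder(), envir = asc_cache)
  get(key, envir = asc_cache)
}

# 150 patients x 2 views = 300 videos at 64x64x16, speckle noise 0.2,
# with a stratified held-out set of 60 videos (6 patients per stage)
get_cohort300 <- function() memo("cohort300", function() {
  specs <- sample_cohort(150, rep(0.2, 5), seed = 11)
  videos <- list(); labels <- NULL
  for (sp in specs) {
    rv <- render_views(sp, resolution = 64, n_frames = 16)
    tr <- cohort_table(list(sp))
    videos <- c(videos, list(rv$plax, rv$psax))
    labels <- rbind(labels, tr, tr)
  }
  n <- length(videos)
  stage_of_video <- rep(vapply(specs, `[[`, character(1), "true_stage"),
                        each = 2)
  held_out <- unlist(lapply(split(seq_len(n), stage_of_video),
                            function(ix) tail(ix, 12)), use.names = FALSE)
  list(specs = specs, videos = videos, labels = labels,
       held_out = sort(held_out),
       train = setdiff(seq_len(n), held_out))
})

get_scorer300 <- function() memo("scorer300", function() {
  co <- get_cohort300()
  train_continuum_model(co$videos[co$train], co$labels[co$train, ],
                        asc_model_config(seed = 5))
})

get_plax_segmenter <- function() memo("plax_seg", function() {
  specs <- sample_cohort(12, rep(0.2, 5), seed = 31)
  train_plax_segmenter(specs, seed = 7)
})

get_doppler_segmenter <- function() memo("doppler_seg", function() {
  specs <- sample_cohort(10, rep(0.2, 5), seed = 41)
  train_doppler_segmenter(specs, seed = 7)
})

held_out_scores <- function() memo("ho_scores", function() {
  co <- get_cohort300()
  scorer <- get_scorer300()
  data.frame(
    idx = co$held_out,
    score = vapply(co$videos[co$held_out],
                   function(v) score_video(scorer, v), numeric(1)),
    stage = co$labels$stage[co$held_out])
})
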