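# Builds a complete synthetic study on disk and returns the config path.
write_demo_study <- function(dir, seed = 1L, rows = 3L, cols = 3L,
                             posts_per_area = 60L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layer <- make_grid_layer(rows, cols, 0.1, c(-112, 40), counties_per_side = 3,
                           layer_name = "tract")
  zip <- make_grid_layer(rows, cols, 0.1, c(-112, 40), counties_per_side = 1,
                         layer_name = "zip")
  vocab <- fixture_vocab()
  withr::with_seed(seed, {
    p_happy <- runif(rows * cols, 0.15, 0.45)
  })
  truth <- make_area_truth(layer, p_happy = p_happy, p_food = 0.15,
                           p_activity = 0.08, n_posts = posts_per_area)
  sim <- simulate_posts(layer, truth, vocab, seed = seed)
  corpus <- simulate_labeled_corpus(800, 0.5, vocab, seed = seed + 1L)
  write_area_layer(layer, file.path(dir, "tract.geojson"))
  write_area_layer(zip, file.path(dir, "zip.geojson"))
  write_posts_jsonl(sim$posts, file.path(dir, "posts.jsonl"))
  readr::write_csv(corpus, file.path(dir, "corpus.csv"))
  cfg <- list(
    posts = file.path(dir, "posts.jsonl"),
    tract_layer = file.path(dir, "tract.geojson"),
    zip_layer = file.path(dir, "zip.geojson"),
    labeled_corpus = file.path(dir, "corpus.csv"),
    food_lexicon = system.file("extdata", "food_lexicon.csv",
                               package = "tweetscape"),
    activity_lexicon = system.file("extdata", "activity_lexicon.csv",
                                   package = "tweetscape"),
    activity_exclusions = system.file("extdata", "activity_exclusions.txt",
                                      package = "tweetscape"),
    out_dir = file.path(dir, "out"),
    cutpoint = 0.5, min_posts = 30, seed = seed,
    # a small demo corpus spreads over ~50 users, so each holds ~2% of posts;
    # the corpus-share outlier rule needs a threshold matched to that scale
    outlier_threshold = 0.05
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
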