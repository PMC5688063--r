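# Small, cheap worlds for unit tests: 20 x 20 grid, one climate
# variable (13 continuous features incl. latitude), so forests fit in
# milliseconds while every mask and series keeps its structure.
small_world_config <- function(seed = 1, ...) {
  world_config(
    grid = grid_spec(-15, -10, -70, -65, 0.25),
    climate_vars = "pre",
    seed = seed,
    ...
  )
}

small_world <- function(seed = 1, ...) {
  generate_world(small_world_config(seed = seed, ...))
}

# Random regression table for forest unit tests.
random_table <- function(n, p = 3, seed = 1, water = FALSE) {
  set.seed(seed)
  d <- tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(stats::runif(n * p), n, p)),
                    paste0("x", seq_len(p))))
  d$y <- stats::rnorm(n, mean = rowSums(d), sd = 0.3)
  if (water) d$water <- stats::runif(n) < 0.3
  d
}
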