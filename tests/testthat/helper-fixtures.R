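# Shared helpers: wrap raw masks as regions, render measured feature
# pools, and cache the default model across tests.

region_from_mask <- function(mask, um_per_pixel = 6.5, region_id = 1L) {
  structure(list(mask = mask,
                 bbox = c(row0 = 0L, col0 = 0L,
                          height = nrow(mask), width = ncol(mask)),
                 area_px = sum(mask), touches_border = FALSE,
                 region_id = region_id, um_per_pixel = um_per_pixel),
            class = "worm_region")
}

rect_mask <- function(h, w) matrix(TRUE, h, w)

measure_generated_worm <- function(spec, seed, um_per_pixel = 6.5) {
  w <- make_worm(spec, seed = seed, um_per_pixel = um_per_pixel)
  list(worm = w, region = region_from_mask(w$mask, um_per_pixel))
}

# features of rendered worms, skipping rejections until n collected
render_feature_pool <- function(counts, seed_base) {
  rows <- list()
  for (cl in names(counts)) {
    got <- 0; s <- seed_base
    spec <- default_worm_specs()[[cl]]
    while (got < counts[[cl]]) {
      s <- s + 1
      g <- measure_generated_worm(spec, seed = s)
      f <- extract_features(g$region)
      if (is_rejection(f)) next
      got <- got + 1
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, length_um = f$length_um, thickness_um = f$thickness_um,
        r1 = f$r1, r2 = f$r2)
    }
  }
  do.call(rbind, rows)
}

cached_default_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) model <<- fit_training(default_training_table())
    model
  }
})
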