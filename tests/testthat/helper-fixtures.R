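# Shared fixtures and independent oracles.

# Independent 8-connectivity component counter (queue flood fill in plain R);
# deliberately separate from the package's C++ labeler.
count_components_oracle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  n <- 0L
  for (w0 in seq_len(W)) for (h0 in seq_len(H)) {
    if (mask[h0, w0] == 0 || seen[h0, w0]) next
    n <- n + 1L
    stack <- list(c(h0, w0)); seen[h0, w0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dh in -1:1) for (dw in -1:1) {
        h <- p[1] + dh; w <- p[2] + dw
        if (h < 1 || h > H || w < 1 || w > W) next
        if (mask[h, w] != 0 && !seen[h, w]) {
          seen[h, w] <- TRUE
          stack[[length(stack) + 1L]] <- c(h, w)
        }
      }
    }
  }
  n
}

# Small multi-seed scene shared by segmentation tests.
make_test_scene <- function(n_seeds = 12, seed = 11) {
  spec <- scene_spec(image_size = c(160, 160), grid = c(4, 4),
                     n_classes = 3, rng_seed = seed)
  generate_scene(spec, class_label = 2, n_seeds = n_seeds, seed = seed)
}

# A purely virtual manifest (no files) for split/enhancement arithmetic.
virtual_manifest <- function(counts, labels = sprintf("class_%d", seq_along(counts))) {
  empty <- data.frame(path = character(), label = character(),
                      split = character(), origin = character())
  if (all(counts == 0)) return(empty)
  do.call(rbind, lapply(seq_along(counts), function(i) {
    n <- counts[i]
    if (n == 0) return(NULL)
    data.frame(path = sprintf("img_%s_%05d.png", labels[i], seq_len(n)),
               label = labels[i], split = NA_character_, origin = "original")
  }))
}

# Per-class published dataset sizes (effective images) used in arithmetic tests.
effective_counts <- c(1034L, 881L, 839L, 860L, 917L, 685L, 808L, 954L)
seed_class_names <- c("BLC", "GL07C", "GL13C", "JL05C", "JL09C", "JL10C",
                      "JL11C", "JL06C")

# Tiny network spec used where a full backbone would be wasteful.
tiny_stages <- function() data.frame(t = c(1, 6), c = c(8, 12), n = c(1, 1),
                                     s = c(1, 2))
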