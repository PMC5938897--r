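# Synthetic handwritten-looking X/O glyphs and the k-NN mark classifier.
#
# The original training handwriting is not distributable, so the
# classifier trains on generated glyphs: X = two jittered, slightly bowed
# strokes; O = a perturbed ellipse with occasional gaps. Style parameters
# scale with a `jitter` level (1 = nominal); higher levels add endpoint
# wander, thin strokes and salt-and-pepper flips, degrading legibility.

GLYPH_SIZE <- 20L

# draw one glyph into a white h x w canvas (0 = ink); uses current RNG
draw_glyph <- function(label, h, w, jitter = 1) {
  img <- matrix(255, h, w)
  s <- min(h, w)
  thick <- max(1, s * runif(1, 0.10, 0.16) / max(1, 1 + 0.25 * (jitter - 1)))
  jit <- function(scale) rnorm(1, 0, 0.02 * scale * jitter)
  if (label == "X") {
    for (d in 1:2) {
      mx <- runif(2, 0.08, 0.22) + c(jit(1), jit(1))
      my <- runif(2, 0.08, 0.22) + c(jit(1), jit(1))
      if (d == 1) { x0 <- mx[1] * w; y0 <- my[1] * h; x1 <- (1 - mx[2]) * w; y1 <- (1 - my[2]) * h }
      else        { x0 <- (1 - mx[1]) * w; y0 <- my[1] * h; x1 <- mx[2] * w; y1 <- (1 - my[2]) * h }
      # quadratic bezier with a small random bow
      bow <- runif(1, -0.08, 0.08) * jitter * s
      cx <- (x0 + x1) / 2 + bow; cy <- (y0 + y1) / 2 - bow
      t <- seq(0, 1, length.out = 24)
      xs <- (1 - t)^2 * x0 + 2 * t * (1 - t) * cx + t^2 * x1
      ys <- (1 - t)^2 * y0 + 2 * t * (1 - t) * cy + t^2 * y1
      img <- draw_thick_path(img, xs, ys, thick)
    }
  } else if (label == "O") {
    cx <- w * (0.5 + jit(1) * 2); cy <- h * (0.5 + jit(1) * 2)
    rx <- runif(1, 0.26, 0.36) * w
    ry <- runif(1, 0.26, 0.36) * h
    rot <- runif(1, -25, 25) * pi / 180
    ph <- runif(2, 0, 2 * pi)
    amp <- 0.05 * jitter
    gap <- runif(1) < 0.07 * jitter
    th <- seq(0, 2 * pi, length.out = 90)
    if (gap) {
      g0 <- runif(1, 0, 2 * pi); gw <- runif(1, 0.15, 0.25 + 0.1 * jitter)
      keep <- ((th - g0) %% (2 * pi)) > gw
      th <- th[keep]
    }
    pert <- 1 + amp * sin(2 * th + ph[1]) + amp / 2 * sin(3 * th + ph[2])
    ex <- rx * pert * cos(th); ey <- ry * pert * sin(th)
    xs <- cx + ex * cos(rot) - ey * sin(rot)
    ys <- cy + ex * sin(rot) + ey * cos(rot)
    img <- draw_thick_path(img, xs, ys, thick)
  } else stop_updown("updown_domain", "glyph label must be X or O")
  # stray-pixel noise grows quadratically with jitter
  pflip <- 0.004 * max(0, jitter - 1)^2
  if (pflip > 0) {
    flips <- which(runif(length(img)) < pflip)
    img[flips] <- 255 - img[flips]
  }
  img
}

#' Canonicalize a binary patch for classification
#'
#' Crops to the ink bounding box and area-resizes (aspect-normalizing, as
#' usual in glyph OCR: marks squeezed by flat or narrow cells regain their
#' shape) to the canonical 20 x 20 binary patch.
#'
#' @param bin binary 0/1 matrix (1 = ink).
#' @return 20 x 20 binary matrix.
#' @export
canonical_patch <- function(bin) {
  on <- which(bin != 0, arr.ind = TRUE)
  if (nrow(on) == 0) return(matrix(0, GLYPH_SIZE, GLYPH_SIZE))
  crop <- bin[min(on[, 1]):max(on[, 1]), min(on[, 2]):max(on[, 2]), drop = FALSE]
  (resize_area(crop, GLYPH_SIZE, GLYPH_SIZE) > 0.3) * 1
}

#' Generate labelled synthetic glyph samples
#'
#' Deterministic for a given seed: `n_per_class` X and O glyphs drawn at
#' random native sizes and canonicalized like real cell patches.
#'
#' @param n_per_class samples per class (>= 1).
#' @param seed integer seed.
#' @param jitter style jitter level (1 = nominal handwriting).
#' @param size_range native glyph canvas sizes (px) to draw at.
#' @return list with `patches` (list of 20x20 binaries) and `labels`
#'   (character vector of `"X"`/`"O"`).
#' @export
generate_glyphs <- function(n_per_class, seed, jitter = 1,
                            size_range = c(16, 56)) {
  if (n_per_class < 1) stop_updown("updown_domain", "n_per_class must be >= 1")
  with_seed(seed, {
    labels <- rep(c("X", "O"), each = n_per_class)
    patches <- lapply(labels, function(lab) {
      h <- sample(seq(size_range[1], size_range[2]), 1)
      w <- sample(seq(size_range[1], size_range[2]), 1)
      canonical_patch((draw_glyph(lab, h, w, jitter) < 128) * 1)
    })
    list(patches = patches, labels = labels)
  })
}

#' Extract a feature vector from a canonical patch
#'
#' Schemes: `"A"` = flattened 20x20 binary (400-d); `"B"` = 4x4 zone ink
#' densities (16-d); `"C"` = 8-bin stroke-orientation histogram of gradient
#' angles, magnitude-weighted and L1-normalized.
#'
#' @param patch 20x20 binary matrix (foreground = 1).
#' @param scheme `"A"`, `"B"` or `"C"`.
#' @return numeric feature vector.
#' @export
extract_features <- function(patch, scheme) {
  switch(scheme,
    A = as.numeric(patch),
    B = as.numeric(resize_area(patch, 4, 4)),
    C = {
      p <- blur3(blur3(patch))  # orientation needs smooth gradients
      gx <- cbind(p[, 2] - p[, 1], (p[, -(1:2)] - p[, 1:(ncol(p) - 2)]) / 2,
                  p[, ncol(p)] - p[, ncol(p) - 1])
      gy <- rbind(p[2, ] - p[1, ], (p[-(1:2), ] - p[1:(nrow(p) - 2), ]) / 2,
                  p[nrow(p), ] - p[nrow(p) - 1, ])
      mag <- sqrt(gx^2 + gy^2)
      ang <- atan2(gy, gx) %% pi
      bin <- pmin(floor(ang / (pi / 8)) + 1, 8)
      v <- vapply(1:8, function(b) sum(mag[bin == b]), numeric(1))
      if (sum(v) > 0) v / sum(v) else v
    },
    stop_updown("updown_domain", "unknown feature scheme '%s'", scheme))
}

feature_matrix <- function(patches, scheme)
  do.call(rbind, lapply(patches, extract_features, scheme = scheme))

# deterministic k-NN: squared Euclidean distances via BLAS; the
# neighbourhood includes every training point tied with the k-th distance,
# so predictions are invariant to training-set order. Vote ties go to the
# class with the smaller summed neighbour distance, then alphabetically.
knn_predict <- function(train, labels, query, k) {
  d2 <- outer(rowSums(query^2), rowSums(train^2), `+`) - 2 * query %*% t(train)
  classes <- sort(unique(labels))
  apply(d2, 1, function(r) {
    kth <- sort(r, partial = k)[k]
    sel <- which(r <= kth + 1e-9)
    votes <- vapply(classes, function(cl) sum(labels[sel] == cl), numeric(1))
    top <- classes[votes == max(votes)]
    if (length(top) > 1) {
      sums <- vapply(top, function(cl) sum(r[sel][labels[sel] == cl]), numeric(1))
      top <- top[sums == min(sums)]
    }
    top[1]
  })
}

#' Train the k-NN mark ensemble
#'
#' Three members by default (flattened pixels with k = 3, zone densities
#' with k = 5, orientation histogram with k = 3) voting by simple majority.
#'
#' @param samples output of [generate_glyphs()] (or the same structure
#'   built from real scans).
#' @param members list of `list(scheme, k)` member definitions; must have
#'   an odd count >= 3.
#' @return object of class `mark_ensemble`.
#' @export
train_ensemble <- function(samples,
                           members = list(list(scheme = "A", k = 3L),
                                          list(scheme = "B", k = 5L),
                                          list(scheme = "C", k = 3L))) {
  if (length(unique(samples$labels)) < 2)
    stop_updown("updown_training", "training set must contain both classes")
  if (length(members) < 3 || length(members) %% 2 == 0)
    stop_updown("updown_config", "ensemble needs an odd number of members >= 3")
  fitted <- lapply(members, function(mb)
    list(scheme = mb$scheme, k = as.integer(mb$k),
         train = feature_matrix(samples$patches, mb$scheme)))
  structure(list(members = fitted, labels = samples$labels, version = "1"),
            class = "mark_ensemble")
}

#' @export
print.mark_ensemble <- function(x, ...) {
  cat(sprintf("<mark_ensemble: %d members (%s), %d training samples>\n",
              length(x$members),
              paste(vapply(x$members, function(m)
                sprintf("%s/k=%d", m$scheme, m$k), character(1)), collapse = ", "),
              length(x$labels)))
  invisible(x)
}

# batch classification of canonical patches; returns labels + vote agreement
predict_ensemble <- function(ensemble, patches) {
  if (length(patches) == 0)
    return(list(label = character(0), agreement = numeric(0)))
  votes <- vapply(ensemble$members, function(mb) {
    q <- feature_matrix(patches, mb$scheme)
    knn_predict(mb$train, ensemble$labels, q, mb$k)
  }, character(length(patches)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  label <- apply(votes, 1, function(v) names(which.max(table(v))))
  agreement <- apply(votes, 1, function(v) max(table(v))) / length(ensemble$members)
  list(label = label, agreement = agreement)
}

#' Classify one cell patch as X, O or empty
#'
#' The empty decision is made first, from the ink fraction of the raw
#' binarized patch; only inked patches reach the k-NN vote.
#'
#' @param cell_image binary 0/1 cell patch (native size).
#' @param ensemble a `mark_ensemble`.
#' @param ink_threshold minimum ink fraction for a mark (default 0.02).
#' @return `"X"`, `"O"` or `"."` (empty).
#' @export
classify_cell <- function(cell_image, ensemble, ink_threshold = 0.02) {
  if (ink_fraction(cell_image) < ink_threshold) return(".")
  predict_ensemble(ensemble, list(canonical_patch(cell_image)))$label
}

#' Save / load a trained ensemble as JSON
#' @param ensemble a `mark_ensemble`.
#' @param path archive path.
#' @return `path` (save) or a `mark_ensemble` (load).
#' @export
save_ensemble <- function(ensemble, path) {
  ser <- list(version = ensemble$version, labels = ensemble$labels,
              members = lapply(ensemble$members, function(m)
                list(scheme = m$scheme, k = m$k,
                     dim = dim(m$train), train = as.vector(m$train))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- lapply(seq_len(nrow(obj$members)), function(i) {
    m <- obj$members[i, ]
    list(scheme = m$scheme, k = as.integer(m$k),
         train = matrix(unlist(m$train), nrow = unlist(m$dim)[1]))
  })
  structure(list(members = members, labels = obj$labels, version = obj$version),
            class = "mark_ensemble")
}

# session-cached default ensemble trained on nominal synthetic glyphs
default_ensemble <- function() {
  if (is.null(.updown_env$ensemble))
    .updown_env$ensemble <- train_ensemble(generate_glyphs(400, seed = 860201, jitter = 1))
  .updown_env$ensemble
}
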