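# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures live in the repository.

# a filled disk mask in an h x w image
disk_mask <- function(h, w, row, col, radius) {
  d <- outer(seq_len(h) - row, rep(1, w))^2 +
    outer(rep(1, h), seq_len(w) - col)^2
  d <= radius^2
}

# fluorescence pair with two disks; green_frac scales green relative to blue
two_disk_pair <- function(h = 64, w = 64, r = 8,
                          centers = list(c(20, 20), c(44, 44)),
                          green_frac = c(0, 1), blue_level = 0.8) {
  blue <- matrix(0, h, w)
  green <- matrix(0, h, w)
  for (i in seq_along(centers)) {
    m <- disk_mask(h, w, centers[[i]][1], centers[[i]][2], r)
    blue[m] <- blue_level
    green[m] <- green_frac[i] * blue_level
  }
  fluor_pair(blue, green)
}

# semantic map with disks of given classes (0 live / 1 dead)
disk_semantic_map <- function(h = 64, w = 64, r = 8,
                              centers = list(c(20, 20), c(44, 44)),
                              classes = c(0L, 1L)) {
  lab <- matrix(2L, h, w)
  for (i in seq_along(centers)) {
    m <- disk_mask(h, w, centers[[i]][1], centers[[i]][2], r)
    lab[m] <- classes[i]
  }
  semantic_map(lab)
}

# one-hot H x W x 3 probability array that puts probability 1 on `labels`
probs_from_labels <- function(labels) {
  p <- array(0, c(nrow(labels), ncol(labels), 3))
  for (c in 0:2) p[, , c + 1][labels == c] <- 1
  p
}

# Independent brute-force oracle for object_confusion: enumerate ground-truth
# connected components by repeated flood fill over an R matrix, vote by
# counting labels pixel by pixel. Deliberately avoids the package's C++
# labeling and tally code paths.
brute_object_confusion <- function(gt, pred, min_area = 1) {
  gt <- unclass(gt)
  pred <- unclass(pred)
  h <- nrow(gt); w <- ncol(gt)
  seen <- matrix(FALSE, h, w)
  counts <- matrix(0L, 2, 2, dimnames = list(pred = c("live", "dead"),
                                             gt = c("live", "dead")))
  missed <- c(live = 0L, dead = 0L)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (seen[i, j] || gt[i, j] == 2L) next
    # flood fill (8-connectivity) collecting the component
    stack <- list(c(i, j))
    comp <- matrix(numeric(0), ncol = 2)
    seen[i, j] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      comp <- rbind(comp, cur)
      for (di in -1:1) for (dj in -1:1) {
        ni <- cur[1] + di; nj <- cur[2] + dj
        if (ni < 1 || ni > h || nj < 1 || nj > w) next
        if (!seen[ni, nj] && gt[ni, nj] != 2L) {
          seen[ni, nj] <- TRUE
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
    if (nrow(comp) < min_area) next
    gt_lab <- gt[comp]
    gt_cls <- if (sum(gt_lab == 1L) >= sum(gt_lab == 0L)) "dead" else "live"
    pr <- pred[comp]
    if (sum(pr == 2L) > nrow(comp) / 2) {
      missed[gt_cls] <- missed[gt_cls] + 1L
    } else {
      vote <- if (sum(pr == 1L) >= sum(pr == 0L)) "dead" else "live"
      counts[vote, gt_cls] <- counts[vote, gt_cls] + 1L
    }
  }
  list(counts = counts, missed = missed)
}

# small random three-class scene with blob-ish objects for property tests
random_scene <- function(seed, h = 48, w = 48, n_obj_max = 6) {
  set.seed(seed)
  lab <- matrix(2L, h, w)
  n <- sample.int(n_obj_max, 1)
  for (i in seq_len(n)) {
    r <- sample(5:(h - 5), 1)
    c <- sample(5:(w - 5), 1)
    rad <- sample(2:4, 1)
    lab[disk_mask(h, w, r, c, rad)] <- sample(0:1, 1)
  }
  semantic_map(lab)
}

# corrupt a semantic map: flip object classes / erase objects at random
perturb_scene <- function(map, seed) {
  set.seed(seed)
  lab <- unclass(map)
  comp <- phaseviab:::label_components_cpp(lab != 2L)
  if (max(comp) > 0) {
    for (id in seq_len(max(comp))) {
      u <- runif(1)
      px <- comp == id
      if (u < 0.2) {
        lab[px] <- 2L                      # erase -> missed
      } else if (u < 0.5) {
        lab[px] <- 1L - lab[px][1]         # flip class
      }
    }
  }
  semantic_map(lab)
}
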