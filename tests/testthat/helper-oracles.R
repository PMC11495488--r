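# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force Otsu: exhaustive scan over all candidate thresholds,
# maximizing between-class variance, midpoint tie-break.
oracle_otsu <- function(values) {
  v <- round(values)
  lv <- sort(unique(v))
  best <- -Inf
  winners <- numeric()
  n <- length(v)
  for (i in seq_len(length(lv) - 1)) {
    t <- lv[i]
    bg <- v[v <= t]
    fg <- v[v > t]
    w0 <- length(bg) / n
    w1 <- length(fg) / n
    bcv <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      winners <- i
    } else if (bcv > best - 1e-12) {
      winners <- c(winners, i)
    }
  }
  # midpoint of the full range of real thresholds achieving the maximum
  (lv[min(winners)] + lv[max(winners) + 1]) / 2
}

# igraph-based connected components of a binary 3-D array.
# Returns integer labels (0 = background).
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- array(seq_along(mask), dim = d)
  offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  offs <- offs[!(offs$a == 0 & offs$b == 0 & offs$c == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$a) + abs(offs$b) + abs(offs$c) == 1, ]
  }
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    a <- offs$a[i]; b <- offs$b[i]; cc <- offs$c[i]
    y1 <- max(1, 1 + a):min(d[1], d[1] + a)
    x1 <- max(1, 1 + b):min(d[2], d[2] + b)
    z1 <- max(1, 1 + cc):min(d[3], d[3] + cc)
    from <- idx[y1, x1, z1, drop = FALSE]
    to <- idx[y1 - a, x1 - b, z1 - cc, drop = FALSE]
    keep <- mask[from] & mask[to]
    if (any(keep)) edges[[length(edges) + 1]] <- cbind(from[keep], to[keep])
  }
  nodes <- which(mask)
  g <- igraph::graph_from_edgelist(
    matrix(match(do.call(rbind, c(list(matrix(0L, 0, 2)), edges)), nodes),
           ncol = 2),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0, length(nodes) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab <- array(0L, dim = d)
  lab[nodes] <- comp
  lab
}

# Flood-fill purify oracle: keep the largest 26-connected foreground
# component, then fill 6-connected background components that never touch
# the array boundary.
oracle_purify <- function(mask) {
  d <- dim(mask)
  lab <- oracle_label(mask != 0, 26)
  sizes <- tabulate(lab[lab > 0])
  out <- lab == which.max(sizes)
  blab <- oracle_label(!out, 6)
  touching <- unique(c(blab[1, , ], blab[d[1], , ], blab[, 1, ],
                       blab[, d[2], ], blab[, , 1], blab[, , d[3]]))
  out[blab > 0 & !(blab %in% touching)] <- TRUE
  out
}

# Hand-formula Kruskal-Wallis H with tie correction.
oracle_kruskal <- function(values, groups) {
  groups <- as.factor(groups)
  n <- length(values)
  rk <- rank(values)
  rsum <- tapply(rk, groups, sum)
  ng <- tapply(rk, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / ng) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Hand-formula Dunn z for one pair of groups.
oracle_dunn_z <- function(values, groups, a, b) {
  n <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  ra <- mean(rk[groups == a])
  rb <- mean(rk[groups == b])
  na <- sum(groups == a)
  nb <- sum(groups == b)
  (ra - rb) / sqrt((n * (n + 1) / 12 - tie_term) * (1 / na + 1 / nb))
}

# Segmented spherical ROI built straight from a rod phantom (binary input,
# largest inscribed sphere minus a margin).
make_segmented_phantom <- function(shape = c(64, 64, 64), target_bvtv = 0.3,
                                   strut_radius = 3, kappa = 0,
                                   mean_axis = c(0, 0, 1), seed = 1,
                                   voxel_size = 30) {
  gen <- generate_rod_phantom(phantom_spec(
    shape = shape, voxel_size = voxel_size, target_bvtv = target_bvtv,
    strut_radius = strut_radius, mean_axis = mean_axis, kappa = kappa,
    seed = seed
  ))
  d <- dim(gen$volume$values)
  roi <- spherical_roi((c(d[2], d[1], d[3]) - 1) / 2, min(d) / 2 - 2)
  list(seg = segment_roi(gen$volume, roi), truth = gen$truth,
       volume = gen$volume)
}
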