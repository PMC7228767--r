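#' Nearest-neighbour distances between two synapse sets
#'
#' For every query synapse, the minimum distance to any admissible reference
#' synapse, in micrometres. With `group_by_post` (the default, matching how
#' AC-to-ribbon proximity is quantified) queries are compared only against
#' references on the same postsynaptic cell. The `euclidean` metric uses
#' physical positions; `geodesic_on_post_arbor` measures along the shared
#' postsynaptic arbor between the synapse-bearing nodes (and requires
#' `group_by_post` plus a forest). Queries with an empty admissible reference
#' set are excluded from the sample and counted in `n_excluded`.
#'
#' @param query,reference synapse tables (rows of [build_synapse_table()])
#' @param metric "euclidean" or "geodesic_on_post_arbor"
#' @param group_by_post compare within a shared postsynaptic cell only
#' @param forest required for the geodesic metric
#' @return object of class `distance_sample`: list(distances_um, metric,
#'   n_query, n_excluded)
#' @export
nn_distances <- function(query, reference, metric = c("euclidean", "geodesic_on_post_arbor"),
                         group_by_post = TRUE, forest = NULL) {
  metric <- match.arg(metric)
  if (metric == "geodesic_on_post_arbor") {
    if (!group_by_post)
      stopf("geodesic distances are only defined on a shared postsynaptic arbor")
    if (is.null(forest)) stopf("the geodesic metric needs the forest")
  }
  d <- numeric(0)
  n_excl <- 0L
  groups <- if (group_by_post) split(seq_len(nrow(query)), query$post_id)
            else list(all = seq_len(nrow(query)))
  for (g in names(groups)) {
    qi <- groups[[g]]
    ri <- if (group_by_post) which(!is.na(reference$post_id) &
                                     reference$post_id == as.integer(g))
          else seq_len(nrow(reference))
    if (!length(ri)) { n_excl <- n_excl + length(qi); next }
    if (metric == "euclidean") {
      Q <- cbind(query$x_nm[qi], query$y_nm[qi], query$z_nm[qi])
      R <- cbind(reference$x_nm[ri], reference$y_nm[ri], reference$z_nm[ri])
      d <- c(d, vapply(seq_len(nrow(Q)), function(i)
        sqrt(min((R[, 1] - Q[i, 1])^2 + (R[, 2] - Q[i, 2])^2 +
                   (R[, 3] - Q[i, 3])^2)), numeric(1)) / 1000)
    } else {
      sk <- forest$skeletons[[g]]
      if (is.null(sk)) stopf("postsynaptic skeleton %s not in forest", g)
      for (q in qi) {
        if (is.na(query$post_node[q])) { n_excl <- n_excl + 1L; next }
        dm <- geodesic_from(sk, query$post_node[q], forest$scale)
        dr <- dm[as.character(reference$post_node[ri])]
        if (all(is.na(dr))) { n_excl <- n_excl + 1L; next }
        d <- c(d, min(dr, na.rm = TRUE))
      }
    }
  }
  structure(list(distances_um = d, metric = metric,
                 n_query = nrow(query), n_excluded = n_excl),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf("<distance_sample> n=%d (%d excluded), metric=%s, median=%.3g um\n",
              length(x$distances_um), x$n_excluded, x$metric, nn_median(x)))
  invisible(x)
}

sample_dists <- function(sample) {
  d <- if (inherits(sample, "distance_sample")) sample$distances_um
       else as.numeric(sample)
  if (!length(d)) stopf("empty distance sample")
  d
}

#' Empirical CDF and summary statistics of a distance sample
#'
#' `nn_ecdf` returns the right-continuous empirical CDF; `fraction_within(r)`
#' is the fraction of distances `<= r` (closed boundary); `nn_median` uses the
#' lower of the two middle order statistics at even n (a fixed, documented
#' convention).
#'
#' @param sample a `distance_sample` or numeric vector (micrometres)
#' @param r radius in micrometres
#' @return step function / fraction / micrometres
#' @export
nn_ecdf <- function(sample) stats::ecdf(sample_dists(sample))

#' @rdname nn_ecdf
#' @export
fraction_within <- function(sample, r) mean(sample_dists(sample) <= r)

#' @rdname nn_ecdf
#' @export
nn_median <- function(sample) {
  d <- sort(sample_dists(sample))
  d[floor((length(d) + 1) / 2)]
}

#' Stratification-depth profile of a skeleton
#'
#' Apportions each edge's physical cable length to normalized-depth bins
#' (half-open `[lo, hi)`) by linear interpolation between its endpoint
#' depths: an edge spanning a bin boundary splits proportionally. The summed
#' bin mass equals the skeleton's cable length; `density` normalizes to 1.
#'
#' @param sk a [skeleton()]
#' @param frame an [ipl_frame()]
#' @param scale a [voxel_scale()]
#' @param bin_width depth units (default 0.1); bin edges are aligned to
#'   multiples of the width
#' @return data.frame(bin_lo, bin_hi, length_um, density) of class
#'   `strat_profile`; total cable length in `attr(, "total_um")`
#' @export
stratification_profile <- function(sk, frame, scale, bin_width = 0.1) {
  if (bin_width <= 0) stopf("bin_width must be > 0")
  p <- node_phys(sk, scale)
  dep <- ipl_depth(p, frame)
  names(dep) <- rownames(p)
  if (!nrow(sk$edges)) {
    prof <- data.frame(bin_lo = numeric(), bin_hi = numeric(),
                       length_um = numeric(), density = numeric())
    return(structure(prof, class = c("strat_profile", "data.frame"),
                     total_um = 0))
  }
  d1 <- dep[as.character(sk$edges$source)]
  d2 <- dep[as.character(sk$edges$target)]
  a <- p[as.character(sk$edges$source), , drop = FALSE]
  b <- p[as.character(sk$edges$target), , drop = FALSE]
  len <- sqrt(rowSums((a - b)^2)) / 1000
  lo <- pmin(d1, d2); hi <- pmax(d1, d2)
  kmin <- floor(min(lo) / bin_width)
  kmax <- floor(max(hi) / bin_width)
  edges_lo <- (kmin:kmax) * bin_width
  mass <- numeric(length(edges_lo))
  for (e in seq_along(len)) {
    if (hi[e] == lo[e]) {
      k <- floor(lo[e] / bin_width) - kmin + 1
      mass[k] <- mass[k] + len[e]
    } else {
      span <- hi[e] - lo[e]
      ov <- pmax(0, pmin(hi[e], edges_lo + bin_width) - pmax(lo[e], edges_lo))
      mass <- mass + len[e] * ov / span
    }
  }
  nz <- which(mass > 0)
  keep <- if (length(nz)) nz[1]:nz[length(nz)] else integer()  # trim empty rims
  prof <- data.frame(bin_lo = edges_lo[keep], bin_hi = edges_lo[keep] + bin_width,
                     length_um = mass[keep],
                     density = if (sum(mass) > 0) mass[keep] / sum(mass)
                               else mass[keep])
  rownames(prof) <- NULL
  structure(prof, class = c("strat_profile", "data.frame"),
            total_um = sum(len))
}

#' Default depth windows for the ON cone bipolar classifier
#'
#' The windows are configuration, not anatomical claims: the shipped defaults
#' place the type 6 peak just vitreal to the ON SAC plane (depth 1 in SAC
#' units) and types 7/8 progressively deeper, with type 5 peaking at or just
#' sclerad to the plane.
#'
#' @return list of rule parameters
#' @export
default_cb_rules <- function() {
  list(inner_min = 0.8,        # profile mass below this depth is not terminal
       min_frac_inner = 0.25,  # minimum mass fraction at depth >= inner_min
       windows = list(ON_CB5 = c(0.80, 1.05), ON_CB6 = c(1.05, 1.35),
                      ON_CB7 = c(1.35, 1.65), ON_CB8 = c(1.65, 3.0)))
}

#' Classify an ON cone bipolar cell from its stratification profile
#'
#' Rule-based decision on the peak-density depth of the axon-terminal
#' profile relative to the ON SAC plane, the fraction of cable at inner-IPL
#' depths and (when supplied) the branch count. Every decision reports the
#' rule that fired.
#'
#' @param profile a [stratification_profile()]
#' @param features optional list (e.g. branch_count), recorded in the audit
#' @param rules see [default_cb_rules()]
#' @return list(type, rule, peak_depth, frac_inner, features)
#' @export
classify_on_cb <- function(profile, features = list(), rules = default_cb_rules()) {
  tot <- sum(profile$length_um)
  inner <- profile$bin_lo >= rules$inner_min
  frac_inner <- if (tot > 0) sum(profile$length_um[inner]) / tot else 0
  decision <- function(type, rule, peak = NA_real_)
    list(type = type, rule = rule, peak_depth = peak,
         frac_inner = frac_inner, features = features)
  if (tot == 0 || !any(inner) || sum(profile$length_um[inner]) == 0)
    return(decision("UNIDENTIFIED", "no inner-IPL mass (not an ON-CB terminal profile)"))
  if (frac_inner < rules$min_frac_inner)
    return(decision("UNIDENTIFIED",
                    sprintf("inner-IPL mass fraction %.2f < %.2f",
                            frac_inner, rules$min_frac_inner)))
  ip <- which(inner)
  peak_bin <- ip[which.max(profile$length_um[ip])]
  peak <- (profile$bin_lo[peak_bin] + profile$bin_hi[peak_bin]) / 2
  for (ty in names(rules$windows)) {
    w <- rules$windows[[ty]]
    if (peak >= w[1] && peak < w[2])
      return(decision(ty, sprintf("peak depth %.2f in %s window [%.2f, %.2f)",
                                  peak, ty, w[1], w[2]), peak))
  }
  decision("UNIDENTIFIED", sprintf("peak depth %.2f outside all windows", peak))
}

#' En-passant ribbon cluster statistics along one axon shaft
#'
#' Single-linkage clustering of ribbon positions at the linking radius;
#' reports per-cluster size and whether all members are apposed to the same
#' postsynaptic cell (the signature of type 6 en-passant ribbon clusters).
#'
#' @param records ribbon synapse rows sharing one presynaptic skeleton
#' @param linking_radius_um default 1
#' @return data.frame(cluster, size, single_target, post_id)
#' @export
en_passant_cluster_stat <- function(records, linking_radius_um = 1) {
  if (length(unique(records$pre_id)) > 1)
    stopf("records span multiple presynaptic skeletons: %s",
          paste(unique(records$pre_id), collapse = ", "))
  if (!nrow(records))
    return(data.frame(cluster = integer(), size = integer(),
                      single_target = logical(), post_id = integer()))
  cl <- single_linkage_clusters(cbind(records$x_nm, records$y_nm, records$z_nm),
                                linking_radius_um * 1000)
  out <- lapply(split(seq_len(nrow(records)), cl), function(g) {
    posts <- unique(records$post_id[g])
    data.frame(size = length(g), single_target = length(posts) == 1,
               post_id = if (length(posts) == 1) posts else NA_integer_)
  })
  res <- do.call(rbind, out)
  res <- data.frame(cluster = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}
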