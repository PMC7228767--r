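#' Parameters of the synthetic skeleton-volume generator
#'
#' The defaults are the stated world the generator emulates: three fully
#' annotated AII amacrine cells, 61 presynaptic amacrine axons pooling 1425
#' output synapses with target mixture 85/12/2/1% over
#' AII/RB/ON_CB/unidentified, a mean of 173 rod-bipolar ribbon inputs per
#' AII, 100 rod-bipolar dyads containing the focal AC in mixture 75/18/7%
#' (AC+AII / AC+A17 / AC+unidentified), two near-parallel SAC planes tilted
#' against the voxel grid, and conventional AC synapses placed at an
#' exponential offset from the nearest ribbon whose median is 2.3 um
#' (scale 2.3/ln 2 um). `allocation = "quota"` reproduces mixtures exactly by
#' largest-remainder rounding; `"multinomial"` draws them randomly.
#'
#' @param n_aii,n_axons,n_rb,n_cb,n_unid,n_a17,n_dac,n_focal population sizes
#'   (`n_focal`: complete focal amacrine cells participating in dyads)
#' @param output_mixture probabilities over AII/RB/ON_CB/UNIDENTIFIED
#' @param n_output_synapses pooled axon output count
#' @param ribbons_per_aii_mean,ribbons_per_aii_sd ribbon inputs per AII
#' @param ac_offset_scale_um exponential scale of AC-synapse offset from the
#'   nearest ribbon
#' @param n_dyads,dyad_mixture rod-bipolar dyads containing the focal AC
#' @param sac_tilt_deg tilt of the SAC planes against the voxel grid
#' @param depth_noise_nm SAC node scatter about their plane
#' @param soma_inputs_per_aii conventional inputs on the AII soma basket
#' @param allocation "quota" or "multinomial"
#' @param seed RNG seed (generation is fully deterministic given the seed)
#' @param scale a [voxel_scale()]
#' @param branches_per_aii,branch_length_um,node_spacing_um,ribbon_spacing_um
#'   stylized AII tuft geometry
#' @param sac_grid,sac_extent_um SAC node cloud geometry
#' @return list of class `synth_params`
#' @export
synth_params <- function(n_aii = 3, n_axons = 61, n_rb = 60, n_cb = 3,
                         n_unid = 2, n_a17 = 1, n_dac = 8, n_focal = 2,
                         output_mixture = c(AII = 0.85, RB = 0.12,
                                            ON_CB = 0.02, UNIDENTIFIED = 0.01),
                         n_output_synapses = 1425,
                         ribbons_per_aii_mean = 173, ribbons_per_aii_sd = 3,
                         ac_offset_scale_um = 2.3 / log(2),
                         n_dyads = 100,
                         dyad_mixture = c(`AC+AII` = 0.75, `AC+A17` = 0.18,
                                          `AC+UNIDENTIFIED` = 0.07),
                         sac_tilt_deg = 5, depth_noise_nm = 50,
                         soma_inputs_per_aii = 17,
                         allocation = c("quota", "multinomial"), seed = 1,
                         scale = voxel_scale(),
                         branches_per_aii = 12, branch_length_um = 300,
                         node_spacing_um = 1, ribbon_spacing_um = 20,
                         sac_grid = 15, sac_extent_um = 300) {
  allocation <- match.arg(allocation)
  p <- as.list(environment())
  probs <- list(output_mixture = output_mixture, dyad_mixture = dyad_mixture)
  bad <- character()
  for (nm in names(probs)) {
    v <- probs[[nm]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
      bad <- c(bad, sprintf("%s must be non-negative and sum to 1", nm))
  }
  counts <- c("n_aii", "n_axons", "n_rb", "n_cb", "n_unid", "n_a17", "n_dac",
              "n_focal", "n_output_synapses", "n_dyads", "soma_inputs_per_aii")
  for (nm in counts) if (p[[nm]] < 0) bad <- c(bad, paste(nm, "must be >= 0"))
  if (n_dyads > 0 && (n_focal < 1 || n_rb < 1 || n_aii < 1 || n_a17 < 1 ||
                      n_unid < 1))
    bad <- c(bad, "n_dyads > 0 needs n_focal, n_rb, n_aii, n_a17, n_unid >= 1")
  if (ac_offset_scale_um <= 0) bad <- c(bad, "ac_offset_scale_um must be > 0")
  if (length(bad)) stopf("invalid synth_params:\n  - %s",
                         paste(bad, collapse = "\n  - "))
  structure(p, class = "synth_params")
}

#' Largest-remainder integer allocation
#'
#' Distributes `n` seats over categories proportional to `probs`: floor the
#' exact quotas, then hand the remaining seats to the largest fractional
#' remainders; ties are broken by listed order.
#'
#' @param n total count
#' @param probs named probabilities (sum 1)
#' @return named integer vector summing to `n`
#' @export
largest_remainder <- function(n, probs) {
  exact <- n * probs / sum(probs)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(exact - base), seq_along(probs))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

allocate_classes <- function(n, probs, mode) {
  counts <- if (mode == "quota") largest_remainder(n, probs)
            else stats::setNames(drop(stats::rmultinom(1, n, probs)), names(probs))
  rep(names(probs), counts)
}

# -- internal skeleton builder ------------------------------------------------

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$things <- list(); env$next_node <- 1L
  env
}

b_thing <- function(b, name) {
  sid <- length(b$things) + 1L
  b$things[[sid]] <- list(name = name, x = numeric(), y = numeric(),
                          z = numeric(), id = integer(), comment = character(),
                          e_from = integer(), e_to = integer(), soma = NULL)
  sid
}

# xyz in micrometres; returns global node ids
b_nodes <- function(b, sid, xyz, comment = NA_character_) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  ids <- seq.int(b$next_node, length.out = n)
  b$next_node <- b$next_node + n
  t <- b$things[[sid]]
  t$x <- c(t$x, xyz[, 1]); t$y <- c(t$y, xyz[, 2]); t$z <- c(t$z, xyz[, 3])
  t$id <- c(t$id, ids)
  t$comment <- c(t$comment, rep_len(as.character(comment), n))
  b$things[[sid]] <- t
  ids
}

b_edges <- function(b, sid, from, to) {
  t <- b$things[[sid]]
  t$e_from <- c(t$e_from, from); t$e_to <- c(t$e_to, to)
  b$things[[sid]] <- t
}

b_chain <- function(b, sid, ids) {
  if (length(ids) > 1) b_edges(b, sid, ids[-length(ids)], ids[-1])
}

b_comment <- function(b, sid, node_id, text) {
  t <- b$things[[sid]]
  t$comment[match(node_id, t$id)] <- text
  b$things[[sid]] <- t
}

b_pos <- function(b, sid, node_id) {
  t <- b$things[[sid]]
  k <- match(node_id, t$id)
  c(t$x[k], t$y[k], t$z[k])
}

# finalize: tilt by rot (3x3, about ctr_um), convert to voxels, build forest
b_forest <- function(b, rot, ctr_um, scale) {
  skels <- list()
  for (sid in seq_along(b$things)) {
    t <- b$things[[sid]]
    p <- cbind(t$x, t$y, t$z)
    p <- sweep(sweep(p, 2, ctr_um) %*% t(rot), 2, ctr_um, `+`) * 1000  # nm
    nodes <- data.frame(node_id = t$id,
                        x = p[, 1] / scale[1], y = p[, 2] / scale[2],
                        z = p[, 3] / scale[3],
                        radius = NA_real_, comment = t$comment,
                        stringsAsFactors = FALSE)
    skels[[as.character(sid)]] <- skeleton(
      sid, t$name, nodes,
      data.frame(source = t$e_from, target = t$e_to),
      soma_node = t$soma, validate = FALSE)
  }
  f <- skeleton_forest(skels, scale)
  anns <- empty_annotations()
  for (sk in f$skeletons) {
    soma <- sk$nodes$node_id[!is.na(sk$nodes$comment) &
                               tolower(sk$nodes$comment) == "soma"]
    if (length(soma)) f$skeletons[[as.character(sk$id)]]$soma_node <- soma[1]
    anns <- rbind(anns, parse_node_annotations(sk$nodes, sk$id,
                                               annotation_pattern()))
  }
  f$annotations <- anns
  f
}

syn_comment <- function(kind, dir, ptype, pid)
  sprintf("syn:%s:%s:%s:cell%d", kind, dir, ptype, pid)

# -- generator ----------------------------------------------------------------

#' Generate a synthetic annotated skeleton volume with ground truth
#'
#' Builds a stylized retinal volume in an untilted scaffold frame — OFF SAC
#' plane at z = 10 um, ON SAC plane at z = 22 um, AII somata above the OFF
#' plane, distal tufts vitreal to the ON plane — annotates every synapse
#' two-sided with matching partner ids, then rotates the whole volume by the
#' declared SAC tilt before emitting voxel coordinates. Deterministic for a
#' fixed seed.
#'
#' @param params a [synth_params()]
#' @return list(forest = [skeleton_forest()], truth = ground-truth list)
#' @export
generate_connectome <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  b <- new_builder()
  z_off <- 10; z_on <- 22; z_tuft <- 26; z_soma <- 7  # um
  ds <- params$node_spacing_um
  L <- params$branch_length_um
  nb <- params$branches_per_aii

  types <- character(); pair_rows <- list()
  add_pair <- function(pre_id, pre_node, post_id, post_node, kind, class)
    pair_rows[[length(pair_rows) + 1L]] <<-
      data.frame(pre_id = pre_id, pre_node = pre_node, post_id = post_id,
                 post_node = post_node, kind = kind, class = class)

  # SAC planes ---------------------------------------------------------------
  gx <- if (params$sac_grid > 0)
    seq(0, params$sac_extent_um, length.out = params$sac_grid) else numeric()
  grid <- as.matrix(expand.grid(x = gx, y = gx))
  sac_ids <- integer()
  for (side in if (nrow(grid)) c("OFF", "ON") else character()) {
    sid <- b_thing(b, sprintf("SAC_%s_cloud", side))
    zz <- (if (side == "OFF") z_off else z_on) +
      stats::rnorm(nrow(grid), 0, params$depth_noise_nm / 1000)
    ids <- b_nodes(b, sid, cbind(grid, zz))
    b_chain(b, sid, ids)
    types[as.character(sid)] <- paste0("SAC_", side)
    sac_ids[side] <- sid
  }

  # AII cells ----------------------------------------------------------------
  aii <- list()
  for (i in seq_len(params$n_aii)) {
    sid <- b_thing(b, sprintf("AII_%d", i))
    ctr <- c(60 + 90 * (i - 1), 150)
    soma_id <- b_nodes(b, sid, c(ctr, z_soma), "soma")
    b$things[[sid]]$soma <- soma_id
    # soma basket collar: one node per basket input
    nI <- params$soma_inputs_per_aii
    collar <- integer()
    if (nI > 0) {
      th <- 2 * pi * seq_len(nI) / nI
      collar <- b_nodes(b, sid, cbind(ctr[1] + 2 * cos(th),
                                      ctr[2] + 2 * sin(th), z_soma))
      b_edges(b, sid, rep(soma_id, nI), collar)
    }
    trunk_z <- seq(z_soma, z_tuft, by = 1)
    trunk <- b_nodes(b, sid, cbind(ctr[1], ctr[2], trunk_z))
    b_chain(b, sid, c(soma_id, trunk))
    hub <- trunk[length(trunk)]
    branches <- list(); dirs <- list()
    for (j in seq_len(nb)) {
      th <- 2 * pi * j / nb
      tt <- seq(ds, L, by = ds)
      ids <- b_nodes(b, sid, cbind(ctr[1] + tt * cos(th),
                                   ctr[2] + tt * sin(th), z_tuft))
      b_chain(b, sid, c(hub, ids))
      branches[[j]] <- ids
      dirs[[j]] <- c(cos(th), sin(th))
    }
    types[as.character(sid)] <- "AII"
    aii[[i]] <- list(sid = sid, soma = soma_id, collar = collar, hub = hub,
                     ctr = ctr, branches = branches, dirs = dirs)
  }
  aii_sids <- vapply(aii, function(a) a$sid, integer(1))

  # supporting populations ----------------------------------------------------
  stick <- function(name, x0, type, z0 = 5, z1 = z_tuft + 2) {
    sid <- b_thing(b, name)
    ids <- b_nodes(b, sid, cbind(x0, 280, seq(z0, z1, length.out = 8)))
    b_chain(b, sid, ids)
    types[as.character(sid)] <<- type
    sid
  }
  rb_sids <- vapply(seq_len(params$n_rb), function(k)
    stick(sprintf("RB_%d", k), 5 + 4 * k, "RB"), integer(1))
  cb_sids <- vapply(seq_len(params$n_cb), function(k)
    stick(sprintf("ON_CB6_%d", k), 260 + 4 * k, "ON_CB6"), integer(1))
  un_sids <- vapply(seq_len(params$n_unid), function(k)
    stick(sprintf("unknown_%d", k), 280 + 4 * k, "UNIDENTIFIED"), integer(1))
  a17_sids <- vapply(seq_len(params$n_a17), function(k)
    stick(sprintf("A17_%d", k), 290 + 4 * k, "A17"), integer(1))
  dac_sids <- vapply(seq_len(params$n_dac), function(k)
    stick(sprintf("DAC_%d", k), 300 + 4 * k, "DAC"), integer(1))
  focal_sids <- vapply(seq_len(params$n_focal), function(k)
    stick(sprintf("NOS1_AC_%d", k), 310 + 4 * k, "NOS1_AC"), integer(1))
  axon_sids <- vapply(seq_len(params$n_axons), function(k) {
    sid <- b_thing(b, sprintf("axon_AC_%d", k))
    types[as.character(sid)] <<- "AC"
    sid
  }, integer(1))

  # rod-bipolar ribbon inputs to AII distal dendrites -------------------------
  slot_arcs <- seq(params$ribbon_spacing_um / 2, L, by = params$ribbon_spacing_um)
  ribbon_sites <- list()   # per AII: data.frame(branch, arc, node)
  n_rib_true <- integer(params$n_aii)
  for (i in seq_len(params$n_aii)) {
    slots <- expand.grid(branch = seq_len(nb), arc = slot_arcs)
    n_rib <- max(0L, min(nrow(slots),
                         round(stats::rnorm(1, params$ribbons_per_aii_mean,
                                            params$ribbons_per_aii_sd))))
    n_rib_true[i] <- n_rib
    take <- slots[sample.int(nrow(slots), n_rib), , drop = FALSE]
    take$node <- NA_integer_
    for (r in seq_len(nrow(take))) {
      ids <- aii[[i]]$branches[[take$branch[r]]]
      k <- max(1L, min(length(ids), round(take$arc[r] / ds)))
      nid <- ids[k]
      take$node[r] <- nid
      rb <- rb_sids[((r - 1) %% params$n_rb) + 1]
      pos <- b_pos(b, aii[[i]]$sid, nid)
      rb_node <- b_nodes(b, rb, pos + c(0, 0, 0.15),
                         syn_comment("ribbon", "out", "AII", aii[[i]]$sid))
      b_edges(b, rb, b$things[[rb]]$id[1], rb_node)
      b_comment(b, aii[[i]]$sid, nid, syn_comment("ribbon", "in", "RB", rb))
      add_pair(rb, rb_node, aii[[i]]$sid, nid, "ribbon", "RB->AII")
    }
    ribbon_sites[[i]] <- take
  }

  # pooled axon outputs -------------------------------------------------------
  classes <- allocate_classes(params$n_output_synapses, params$output_mixture,
                              params$allocation)
  classes <- sample(classes)
  ax_of <- rep_len(seq_len(params$n_axons), length(classes))
  jitter_xy <- function() stats::runif(2, -1, 1)
  for (s in seq_along(classes)) {
    cls <- classes[s]
    ax <- axon_sids[ax_of[s]]
    if (cls == "AII" && params$n_aii > 0) {
      i <- sample.int(params$n_aii, 1)
      sites <- ribbon_sites[[i]]
      if (!nrow(sites)) next
      site <- sites[sample.int(nrow(sites), 1), ]
      r <- stats::rexp(1, 1 / params$ac_offset_scale_um)
      arc <- site$arc + sample(c(-1, 1), 1) * r
      arc <- max(0, min(L, arc))
      # dedicated node at the exact arc position, hooked to the nearest
      # chain node, so the offset model is realized without grid snapping
      dir2 <- aii[[i]]$dirs[[site$branch]]
      pos <- c(aii[[i]]$ctr + arc * dir2, z_tuft)
      nid <- b_nodes(b, aii[[i]]$sid, pos, syn_comment("conv", "in", "AC", ax))
      ids <- aii[[i]]$branches[[site$branch]]
      k <- max(1L, min(length(ids), round(arc / ds)))
      b_edges(b, aii[[i]]$sid, ids[k], nid)
      an <- b_nodes(b, ax, pos + c(0, 0, 0.15),
                    syn_comment("conv", "out", "AII", aii[[i]]$sid))
      add_pair(ax, an, aii[[i]]$sid, nid, "conventional", "axon->AII")
    } else {
      tgt <- switch(cls,
                    RB = rb_sids[sample.int(length(rb_sids), 1)],
                    ON_CB = cb_sids[sample.int(length(cb_sids), 1)],
                    UNIDENTIFIED = un_sids[sample.int(length(un_sids), 1)],
                    NA_integer_)
      if (is.na(tgt)) next
      base <- b_pos(b, tgt, b$things[[tgt]]$id[1])
      pos <- base + c(jitter_xy(), stats::runif(1, 1, 3))
      tn <- b_nodes(b, tgt, pos, syn_comment("conv", "in", "AC", ax))
      b_edges(b, tgt, b$things[[tgt]]$id[1], tn)
      an <- b_nodes(b, ax, pos + c(0, 0, 0.15),
                    syn_comment("conv", "out", types[as.character(tgt)], tgt))
      add_pair(ax, an, tgt, tn, "conventional", paste0("axon->", cls))
    }

  }
  # chain each axon's nodes; give empty axons a stub
  for (k in seq_len(params$n_axons)) {
    t <- b$things[[axon_sids[k]]]
    if (length(t$id) < 2) {
      ids <- b_nodes(b, axon_sids[k], cbind(c(1, 2), 320 + 0.5 * k, z_tuft + 1))
      t <- b$things[[axon_sids[k]]]
    }
    ord <- order(t$x, t$y, t$id)
    b_chain(b, axon_sids[k], t$id[ord])
  }

  # rod-bipolar dyads containing the focal AC ---------------------------------
  dyad_classes <- allocate_classes(params$n_dyads, params$dyad_mixture,
                                   params$allocation)
  dyad_truth <- character(0)
  if (params$n_dyads > 0) {
    dyad_classes <- sample(dyad_classes)
    for (m in seq_along(dyad_classes)) {
      cls <- dyad_classes[m]
      site <- c(5 + 3 * m, 200, z_tuft + 1)
      rb <- rb_sids[((m - 1) %% params$n_rb) + 1]
      fc <- focal_sids[((m - 1) %% length(focal_sids)) + 1]
      partner <- switch(cls,
                        `AC+AII` = aii_sids[((m - 1) %% params$n_aii) + 1],
                        `AC+A17` = a17_sids[((m - 1) %% params$n_a17) + 1],
                        `AC+UNIDENTIFIED` = un_sids[((m - 1) %% params$n_unid) + 1])
      ptype <- types[as.character(partner)]
      ro1 <- b_nodes(b, rb, site + c(-0.1, 0, 0),
                     syn_comment("ribbon", "out", "NOS1_AC", fc))
      ro2 <- b_nodes(b, rb, site + c(0.1, 0, 0),
                     syn_comment("ribbon", "out", ptype, partner))
      b_edges(b, rb, rep(b$things[[rb]]$id[1], 2), c(ro1, ro2))
      # input marks sit directly under their own output mark so greedy
      # proximity pairing has a unique nearest match (no ties)
      fi <- b_nodes(b, fc, site + c(-0.1, -0.15, 0),
                    syn_comment("ribbon", "in", "RB", rb))
      b_edges(b, fc, b$things[[fc]]$id[1], fi)
      pi_ <- b_nodes(b, partner, site + c(0.1, 0.15, 0),
                     syn_comment("ribbon", "in", "RB", rb))
      anchor <- if (cls == "AC+AII") aii[[((m - 1) %% params$n_aii) + 1]]$hub
                else b$things[[partner]]$id[1]
      b_edges(b, partner, anchor, pi_)
      add_pair(rb, ro1, fc, fi, "ribbon", paste0("dyad:", cls))
      add_pair(rb, ro2, partner, pi_, "ribbon", paste0("dyad:", cls))
      dyad_truth <- c(dyad_truth, cls)
    }
  }

  # soma baskets ---------------------------------------------------------------
  if (params$n_dac > 0 && params$soma_inputs_per_aii > 0) {
    for (i in seq_len(params$n_aii)) {
      for (q in seq_len(params$soma_inputs_per_aii)) {
        nid <- aii[[i]]$collar[q]
        dac <- dac_sids[((q - 1) %% params$n_dac) + 1]
        b_comment(b, aii[[i]]$sid, nid, syn_comment("conv", "in", "DAC", dac))
        pos <- b_pos(b, aii[[i]]$sid, nid)
        dn <- b_nodes(b, dac, pos + c(0, 0, -0.15),
                      syn_comment("conv", "out", "AII", aii[[i]]$sid))
        b_edges(b, dac, b$things[[dac]]$id[1], dn)
        add_pair(dac, dn, aii[[i]]$sid, nid, "conventional", "DAC->AII soma")
      }
    }
  }

  # tilt and emit ---------------------------------------------------------------
  th <- params$sac_tilt_deg * pi / 180
  rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  ctr <- c(params$sac_extent_um / 2, params$sac_extent_um / 2, (z_off + z_on) / 2)
  forest <- b_forest(b, rot, ctr, params$scale)

  ref <- (c(ctr[1], ctr[2], z_tuft + 10) - ctr) %*% t(rot) + ctr  # GCL side
  truth <- list(
    params = params,
    types = types,
    sac_ids = sac_ids, aii_ids = aii_sids, axon_ids = axon_sids,
    rb_ids = rb_sids, cb_ids = cb_sids, focal_ids = focal_sids,
    a17_ids = a17_sids, dac_ids = dac_sids, unid_ids = un_sids,
    tilt_deg = params$sac_tilt_deg,
    plane_normal = drop(rot %*% c(0, 0, 1)),
    z_off_um = z_off, z_on_um = z_on, rotation = rot, centre_um = ctr,
    orientation_ref_nm = drop(ref) * 1000,
    mixture_counts = table(factor(classes, levels = names(params$output_mixture))),
    ribbons_per_aii = n_rib_true,
    dyad_counts = table(factor(dyad_truth, levels = names(params$dyad_mixture))),
    pairings = if (length(pair_rows)) do.call(rbind, pair_rows) else NULL)
  list(forest = forest, truth = truth)
}

#' Perturb a generated volume (robustness harness)
#'
#' Applies reproducible position jitter and annotation dropout. The truth
#' record is updated with the indices of dropped annotations.
#'
#' @param forest a [skeleton_forest()]
#' @param truth ground truth from [generate_connectome()]
#' @param jitter_nm isotropic Gaussian position jitter
#' @param dropout probability of deleting each annotation comment
#' @param seed RNG seed
#' @return list(forest, truth)
#' @export
perturb <- function(forest, truth, jitter_nm = 0, dropout = 0, seed = 1) {
  set.seed(seed)
  if (jitter_nm > 0) {
    for (k in seq_along(forest$skeletons)) {
      sk <- forest$skeletons[[k]]
      n <- nrow(sk$nodes)
      sk$nodes$x <- sk$nodes$x + stats::rnorm(n, 0, jitter_nm / forest$scale[1])
      sk$nodes$y <- sk$nodes$y + stats::rnorm(n, 0, jitter_nm / forest$scale[2])
      sk$nodes$z <- sk$nodes$z + stats::rnorm(n, 0, jitter_nm / forest$scale[3])
      forest$skeletons[[k]] <- sk
    }
  }
  dropped <- integer()
  if (dropout > 0 && nrow(forest$annotations)) {
    drop_i <- which(stats::runif(nrow(forest$annotations)) < dropout)
    for (r in drop_i) {
      a <- forest$annotations[r, ]
      sk <- forest$skeletons[[as.character(a$skeleton_id)]]
      sk$nodes$comment[sk$nodes$node_id == a$node_id] <- NA_character_
      forest$skeletons[[as.character(a$skeleton_id)]] <- sk
    }
    dropped <- drop_i
    forest$annotations <- forest$annotations[setdiff(seq_len(nrow(forest$annotations)),
                                                     drop_i), ]
  }
  truth$dropped_annotations <- dropped
  list(forest = forest, truth = truth)
}

#' Generate an ON cone bipolar skeleton from a subtype template
#'
#' Emits a stylized ON-CB: a descending axon plus a horizontal terminal arbor
#' at the template's stratification depth (in SAC units: ON plane = 1), with
#' per-cell and per-node depth noise. Used to exercise the stratification
#' profiler and subtype classifier against ground truth.
#'
#' @param type one of ON_CB5/ON_CB6/ON_CB7/ON_CB8
#' @param id skeleton id
#' @param depth_sd per-cell noise on the template peak depth
#' @param z_off_um,z_on_um scaffold SAC plane heights
#' @return a [skeleton()] (voxel coordinates at the default scale)
#' @export
generate_cb <- function(type = "ON_CB6", id = 1L, depth_sd = 0.05,
                        z_off_um = 10, z_on_um = 22) {
  peaks <- c(ON_CB5 = 0.92, ON_CB6 = 1.20, ON_CB7 = 1.50, ON_CB8 = 1.82)
  nbr <- c(ON_CB5 = 3L, ON_CB6 = 5L, ON_CB7 = 4L, ON_CB8 = 3L)
  if (!type %in% names(peaks)) stopf("unknown ON-CB template: %s", type)
  d0 <- peaks[[type]] + stats::rnorm(1, 0, depth_sd)
  sep <- z_on_um - z_off_um
  z_of_depth <- function(d) z_off_um + d * sep
  b <- new_builder()
  sid <- b_thing(b, sprintf("%s_%d", type, id))
  stem <- b_nodes(b, sid, cbind(0, 0, seq(2, z_of_depth(d0), length.out = 10)))
  b_chain(b, sid, stem)
  hub <- stem[length(stem)]
  for (j in seq_len(nbr[[type]])) {
    th <- 2 * pi * j / nbr[[type]]
    tt <- seq(1, 10, by = 1)
    dep <- d0 + stats::rnorm(length(tt), 0, 0.02)
    ids <- b_nodes(b, sid, cbind(tt * cos(th), tt * sin(th), z_of_depth(dep)))
    b_chain(b, sid, c(hub, ids))
  }
  f <- b_forest(b, diag(3), c(0, 0, 0), voxel_scale())
  sk <- f$skeletons[[1]]
  sk$id <- as.integer(id)
  attr(sk, "true_type") <- type
  sk
}

#' The scaffold IPL frame of the generator, pre- or post-tilt
#'
#' Convenience for tests: the exact frame the generator built its volume in.
#'
#' @param truth ground truth from [generate_connectome()]
#' @param tilted return the frame in the emitted (tilted) coordinates
#' @return an [ipl_frame()]
#' @export
truth_frame <- function(truth, tilted = TRUE) {
  mk <- function(n, p0, rms = 0) plane(n, sum(n * p0), rms)
  if (!tilted) {
    n <- c(0, 0, 1)
    off <- c(0, 0, truth$z_off_um * 1000)
    on <- c(0, 0, truth$z_on_um * 1000)
    ref <- c(0, 0, (truth$z_on_um + 20) * 1000)
  } else {
    rot <- truth$rotation; ctr <- truth$centre_um * 1000
    n <- drop(rot %*% c(0, 0, 1))
    tp <- function(p_um) drop((p_um * 1000 - ctr) %*% t(rot)) + ctr
    off <- tp(c(truth$centre_um[1:2], truth$z_off_um))
    on <- tp(c(truth$centre_um[1:2], truth$z_on_um))
    ref <- truth$orientation_ref_nm
  }
  ipl_frame(mk(n, off), mk(n, on), ref)
}
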