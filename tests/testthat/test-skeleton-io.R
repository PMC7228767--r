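test_that("annotation grammar parses and rejects as specified", {
  rec <- parse_annotation("syn:conv:out:AII:cell41")
  expect_equal(rec, list(syn_kind = "conventional", direction = "output",
                         partner_type = "AII", partner_cell_id = 41L))
  rec <- parse_annotation("SYN:RIBBON:IN:rb")  # case-insensitive, no pid
  expect_equal(rec$syn_kind, "ribbon")
  expect_equal(rec$direction, "input")
  expect_equal(rec$partner_type, "RB")
  expect_true(is.na(rec$partner_cell_id))
  expect_equal(parse_annotation("syn:ribbon:in:ON_CB6:7")$partner_type, "ON_CB6")
  # no-match is a value, not an error
  for (bad in c("soma", "", "syn:conv:out", "syn:gap:in:AII",
                "syn:conv:sideways:AII", "syn:conv:in:NOT_A_TYPE",
                "syn:conv:in:AII:xyz", "prefix syn:conv:in:AII"))
    expect_null(parse_annotation(bad), label = bad)
})

test_that("fuzzed comments never raise", {
  set.seed(42)
  alphabet <- c(letters, LETTERS, 0:9, ":", "_", " ", "!", "<", "&")
  for (i in 1:200) {
    s <- paste(sample(alphabet, sample(0:20, 1), replace = TRUE), collapse = "")
    expect_no_error(parse_annotation(s))
  }
  # structured fuzz around the grammar itself
  kinds <- c("ribbon", "conv", "rib", "")
  dirs <- c("in", "out", "inout", "")
  types <- c("AII", "RB", "XYZ", "")
  for (k in kinds) for (d in dirs) for (ty in types) {
    s <- paste("syn", k, d, ty, sep = ":")
    r <- parse_annotation(s)
    ok <- k %in% c("ribbon", "conv") && d %in% c("in", "out") &&
      ty %in% cell_types()
    expect_identical(!is.null(r), ok, label = s)
  }
})

test_that("read_nml handles the empty and minimal annotated cases", {
  p <- withr::local_tempfile(fileext = ".nml")
  minimal_nml(p, character())
  f <- read_nml(p)
  expect_s3_class(f, "skeleton_forest")
  expect_length(f$skeletons, 0)
  expect_equal(nrow(f$annotations), 0)

  minimal_nml(p, c('<thing id="1" name="AII_1"><nodes>',
                   '<node id="1" x="0" y="0" z="0"/>',
                   '<node id="2" x="0" y="0" z="100" comment="syn:ribbon:in:RB"/>',
                   '</nodes><edges><edge source="1" target="2"/></edges></thing>'))
  f <- read_nml(p)
  expect_length(f$skeletons, 1)
  expect_equal(nrow(f$annotations), 1)
  expect_equal(f$annotations$syn_kind, "ribbon")
  expect_equal(f$annotations$direction, "input")
  expect_equal(f$annotations$partner_type, "RB")
  expect_equal(f$annotations$node_id, 2L)
  # scale read back from the file
  expect_equal(unclass(f$scale), c(sx = 13.2, sy = 13.2, sz = 26))
})

test_that("comments blocks are accepted as an alternative annotation carrier", {
  p <- withr::local_tempfile(fileext = ".nml")
  minimal_nml(p, c('<thing id="3" name="RB_1"><nodes>',
                   '<node id="10" x="1" y="2" z="3"/>',
                   '</nodes><edges/></thing>',
                   '<comments><comment node="10" content="syn:conv:out:AII:cell7"/></comments>'))
  f <- read_nml(p)
  expect_equal(nrow(f$annotations), 1)
  expect_equal(f$annotations$partner_cell_id, 7L)
})

test_that("malformed and invalid inputs give named validation errors", {
  p <- withr::local_tempfile(fileext = ".nml")
  writeLines("<things><thing></things>", p)
  expect_error(read_nml(p))  # xml2 parse error
  # edge referencing a missing node, naming the offender
  minimal_nml(p, c('<thing id="1" name="x"><nodes>',
                   '<node id="1" x="0" y="0" z="0"/>',
                   '</nodes><edges><edge source="1" target="99"/></edges></thing>'))
  expect_error(read_nml(p), "99")
  # a cycle, naming the skeleton
  minimal_nml(p, c('<thing id="5" name="x"><nodes>',
                   '<node id="1" x="0" y="0" z="0"/>',
                   '<node id="2" x="1" y="0" z="0"/>',
                   '<node id="3" x="0" y="1" z="0"/>',
                   '</nodes><edges><edge source="1" target="2"/>',
                   '<edge source="2" target="3"/><edge source="3" target="1"/>',
                   '</edges></thing>'))
  expect_error(read_nml(p), "cycle")
  expect_error(read_nml(p), "5")
  # disconnected things are kept, with a warning
  minimal_nml(p, c('<thing id="1" name="x"><nodes>',
                   '<node id="1" x="0" y="0" z="0"/>',
                   '<node id="2" x="1" y="0" z="0"/>',
                   '</nodes><edges/></thing>'))
  expect_warning(f <- read_nml(p), "components")
  expect_length(f$skeletons, 1)
})

test_that("parsing is lossless: counts in = counts out + itemized rejects", {
  p <- withr::local_tempfile(fileext = ".nml")
  minimal_nml(p, c('<thing id="1" name="x"><nodes>',
                   '<node id="1" x="0" y="0" z="0" comment="syn:conv:in:AC"/>',
                   '<node id="2" x="1" y="0" z="0" comment="branch point"/>',
                   '<node id="3" x="2" y="0" z="0"/>',
                   '</nodes><edges><edge source="1" target="2"/>',
                   '<edge source="2" target="3"/></edges></thing>'))
  f <- read_nml(p)
  log <- attr(f, "parse_log")
  expect_equal(log$n_nodes, 3)
  expect_equal(log$n_annotations, 1)
  expect_equal(log$unmatched_comments, "branch point")
  # the unparsed comment survives on the node
  expect_equal(f$skeletons[["1"]]$nodes$comment[2], "branch point")
})

test_that("write/read round-trips generator output and is byte-stable", {
  set.seed(99)
  for (s in 1:20) {
    gen <- generate_connectome(
      synth_params(n_aii = 1, n_axons = 2, n_rb = 2, n_cb = 1, n_unid = 1,
                   n_a17 = 1, n_dac = 1, n_output_synapses = 10,
                   ribbons_per_aii_mean = 4, ribbons_per_aii_sd = 1,
                   n_dyads = 3, soma_inputs_per_aii = 2, branches_per_aii = 2,
                   branch_length_um = 40, sac_grid = 4, sac_extent_um = 60,
                   seed = s))
    p1 <- withr::local_tempfile(fileext = ".nml")
    p2 <- withr::local_tempfile(fileext = ".nml")
    write_nml(gen$forest, p1)
    f2 <- read_nml(p1)
    expect_length(f2$skeletons, length(gen$forest$skeletons))
    for (id in names(gen$forest$skeletons)) {
      a <- gen$forest$skeletons[[id]]; b <- f2$skeletons[[id]]
      expect_equal(b$name, a$name)
      expect_equal(b$nodes$node_id, a$nodes$node_id)
      expect_equal(b$nodes$x, a$nodes$x, tolerance = 1e-8)
      expect_equal(b$nodes$z, a$nodes$z, tolerance = 1e-8)
      expect_equal(b$edges, a$edges)
      expect_equal(b$soma_node, a$soma_node)
    }
    expect_equal(f2$annotations[order(f2$annotations$node_id), ]$raw_comment,
                 gen$forest$annotations[order(gen$forest$annotations$node_id), ]$raw_comment)
    # byte-stable: writing the re-read forest reproduces the file exactly
    write_nml(f2, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("to_physical multiplies by the anisotropic voxel scale", {
  sc <- voxel_scale(13.2, 13.2, 26)
  expect_equal(to_physical(c(0, 0, 0), sc), c(sx = 0, sy = 0, sz = 0))
  expect_equal(unname(to_physical(c(1, 1, 1), sc)), c(13.2, 13.2, 26))
  expect_equal(unname(to_physical(c(10, 20, 5), sc)), c(132, 264, 130))
  expect_error(voxel_scale(0, 1, 1), "positive")
})

test_that("cable_length: closed forms and invariances", {
  sc <- voxel_scale(13.2, 13.2, 26)
  one <- skeleton(1, nodes = data.frame(node_id = 1, x = 0, y = 0, z = 0))
  expect_equal(cable_length(one, sc), 0)
  two <- skeleton(1, nodes = data.frame(node_id = 1:2, x = 0, y = 0, z = c(0, 100)),
                  edges = data.frame(source = 1, target = 2))
  expect_equal(cable_length(two, sc), 2.6)
  k <- 7
  pth <- path_skeleton(k + 1)
  expect_equal(cable_length(pth, sc), k * 26 / 1000)
  # invariant under re-indexing and edge orientation flips
  flip <- pth
  flip$edges <- data.frame(source = pth$edges$target, target = pth$edges$source)
  expect_equal(cable_length(flip, sc), cable_length(pth, sc))
  relab <- pth
  relab$nodes$node_id <- relab$nodes$node_id + 100
  relab$edges <- relab$edges + 100
  expect_equal(cable_length(relab, sc), cable_length(pth, sc))
})

test_that("path_distance equals the weighted shortest-path oracle on random trees", {
  set.seed(7)
  sc <- voxel_scale()
  for (rep in 1:8) {
    n <- sample(5:200, 1)
    sk <- random_tree_skeleton(n)
    ab <- sample.int(n, 2)
    expect_equal(path_distance(sk, ab[1], ab[2], sc),
                 igraph_path_distance(sk, ab[1], ab[2], sc), tolerance = 1e-9)
  }
  expect_equal(path_distance(sk, 3, 3, sc), 0)
})

test_that("path_distance satisfies the tree triangle equality and component errors", {
  sc <- voxel_scale()
  pth <- path_skeleton(9)
  # node 5 lies on the 2..8 path
  expect_equal(path_distance(pth, 2, 8, sc),
               path_distance(pth, 2, 5, sc) + path_distance(pth, 5, 8, sc))
  disc <- suppressWarnings(
    skeleton(1, nodes = data.frame(node_id = 1:4, x = 0, y = 0, z = 0:3),
             edges = data.frame(source = 1, target = 2)))
  expect_error(path_distance(disc, 1, 4, voxel_scale()), "different connected components")
})

test_that("SWC export writes one 7-column file per skeleton in physical um", {
  f <- skeleton_forest(list(path_skeleton(3)), voxel_scale(1000, 1000, 1000))
  d <- withr::local_tempdir()
  paths <- write_swc(f, d)
  expect_length(paths, 1)
  swc <- read.table(paths[1])
  expect_equal(ncol(swc), 7)
  expect_equal(swc$V2, rep(0, 3))          # type column 0
  expect_equal(swc$V5, c(0, 1, 2))         # z in um
  expect_equal(swc$V7[1], -1)              # root
})
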