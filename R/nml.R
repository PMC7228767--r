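#' Parse a synapse annotation comment
#'
#' Node comments encode synapses with the grammar
#' `syn:<kind>:<dir>:<ptype>[:<pid>]` (case-insensitive), where `kind` is
#' `ribbon` or `conv`, `dir` is `in` or `out`, `ptype` is a cell-type label
#' from the controlled vocabulary ([cell_types()]) and the optional `pid` is a
#' partner skeleton id, with or without a `cell` prefix. Anything else is a
#' no-match, returned as `NULL` — unparseable comments are preserved on the
#' node, never dropped. The grammar is pluggable: pass a different `pattern`
#' with the same capture groups to accept another dialect.
#'
#' @param comment character scalar
#' @param pattern regex with capture groups (kind, dir, ptype, pid)
#' @return list(syn_kind, direction, partner_type, partner_cell_id) or `NULL`
#' @export
#' @examples
#' parse_annotation("syn:conv:out:AII:cell41")
#' parse_annotation("soma")  # NULL
parse_annotation <- function(comment, pattern = annotation_pattern()) {
  if (is.null(comment) || is.na(comment)) return(NULL)
  m <- regmatches(comment, regexec(pattern, comment, ignore.case = TRUE))[[1]]
  if (!length(m)) return(NULL)
  ptype <- canonical_cell_type(m[4])
  if (is.na(ptype)) return(NULL)
  pid <- m[5]
  pid <- if (is.na(pid) || pid == "") NA_integer_ else
    as.integer(sub("^cell", "", pid, ignore.case = TRUE))
  list(syn_kind = if (tolower(m[2]) == "conv") "conventional" else "ribbon",
       direction = if (tolower(m[3]) == "in") "input" else "output",
       partner_type = ptype, partner_cell_id = pid)
}

#' @rdname parse_annotation
#' @export
annotation_pattern <- function() {
  "^syn:(ribbon|conv):(in|out):([A-Za-z0-9_]+?)(?::((?:cell)?[0-9]+))?$"
}

# Vectorised parse over a nodes table; returns annotation rows.
parse_node_annotations <- function(nodes, skeleton_id, pattern) {
  out <- empty_annotations()
  has <- which(!is.na(nodes$comment) & nodes$comment != "")
  for (i in has) {
    rec <- parse_annotation(nodes$comment[i], pattern)
    if (is.null(rec)) next
    out <- rbind(out, data.frame(node_id = nodes$node_id[i],
                                 skeleton_id = skeleton_id,
                                 syn_kind = rec$syn_kind,
                                 direction = rec$direction,
                                 partner_type = rec$partner_type,
                                 partner_cell_id = rec$partner_cell_id,
                                 raw_comment = nodes$comment[i],
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Read a Knossos/webKnossos NML skeleton file
#'
#' Parses the NML dialect: root `<things>`, each `<thing id name>` holding
#' `<nodes>`/`<node id x y z radius comment>` and `<edges>`/`<edge source
#' target>`. A `<comments>` block (inside a thing or at root level) is
#' accepted as an alternative carrier of node comments. A `soma` comment
#' marks the skeleton's soma node. Synapse comments matching the annotation
#' grammar become annotation records; all other comments are kept as raw node
#' text and itemized in the parse log (`attr(x, "parse_log")`) — nothing is
#' silently dropped.
#'
#' @param path NML file path
#' @param scale a [voxel_scale()]; if `NULL`, taken from the file's
#'   `<parameters><scale>` element (error when absent from both)
#' @param pattern annotation grammar regex, see [parse_annotation()]
#' @return a [skeleton_forest()]
#' @export
read_nml <- function(path, scale = NULL, pattern = annotation_pattern()) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  doc <- xml2::read_xml(path)  # malformed XML -> xml2 parse error with line
  if (xml2::xml_name(doc) != "things")
    stopf("%s: root element is <%s>, expected <things>", path, xml2::xml_name(doc))

  if (is.null(scale)) {
    sc <- xml2::xml_find_first(doc, "./parameters/scale")
    if (inherits(sc, "xml_missing"))
      stopf("%s: no <parameters><scale> element and no scale argument", path)
    scale <- voxel_scale(as.numeric(xml2::xml_attr(sc, "x")),
                         as.numeric(xml2::xml_attr(sc, "y")),
                         as.numeric(xml2::xml_attr(sc, "z")))
  }

  skels <- list()
  n_nodes_in <- 0L
  for (thing in xml2::xml_find_all(doc, "./thing")) {
    tid <- as.integer(xml2::xml_attr(thing, "id"))
    tname <- xml2::xml_attr(thing, "name")
    if (is.na(tname)) tname <- paste0("skeleton_", tid)
    nd <- xml2::xml_find_all(thing, "./nodes/node")
    nodes <- data.frame(
      node_id = as.integer(xml2::xml_attr(nd, "id")),
      x = as.numeric(xml2::xml_attr(nd, "x")),
      y = as.numeric(xml2::xml_attr(nd, "y")),
      z = as.numeric(xml2::xml_attr(nd, "z")),
      radius = as.numeric(xml2::xml_attr(nd, "radius")),
      comment = xml2::xml_attr(nd, "comment"),
      stringsAsFactors = FALSE)
    n_nodes_in <- n_nodes_in + nrow(nodes)
    ed <- xml2::xml_find_all(thing, "./edges/edge")
    edges <- data.frame(source = as.integer(xml2::xml_attr(ed, "source")),
                        target = as.integer(xml2::xml_attr(ed, "target")))
    # thing-level comments block
    for (cm in xml2::xml_find_all(thing, "./comments/comment")) {
      nid <- as.integer(xml2::xml_attr(cm, "node"))
      nodes$comment[nodes$node_id == nid] <- xml2::xml_attr(cm, "content")
    }
    skels[[as.character(tid)]] <-
      skeleton(tid, tname, nodes, edges, validate = FALSE)
  }

  # root-level comments apply to whichever thing owns the node id
  for (cm in xml2::xml_find_all(doc, "./comments/comment")) {
    nid <- as.integer(xml2::xml_attr(cm, "node"))
    for (k in seq_along(skels)) {
      hit <- skels[[k]]$nodes$node_id == nid
      if (any(hit)) { skels[[k]]$nodes$comment[hit] <- xml2::xml_attr(cm, "content"); break }
    }
  }

  anns <- empty_annotations()
  unmatched <- character()
  for (k in seq_along(skels)) {
    sk <- skels[[k]]
    validate_skeleton(sk)
    soma <- sk$nodes$node_id[!is.na(sk$nodes$comment) &
                               tolower(sk$nodes$comment) == "soma"]
    if (length(soma)) skels[[k]]$soma_node <- soma[1]
    a <- parse_node_annotations(sk$nodes, sk$id, pattern)
    anns <- rbind(anns, a)
    cm <- sk$nodes$comment
    other <- cm[!is.na(cm) & cm != "" & tolower(cm) != "soma" &
                  !(sk$nodes$node_id %in% a$node_id)]
    unmatched <- c(unmatched, other)
  }

  # volume bounds, if declared
  bb <- xml2::xml_find_first(doc, "./parameters/boundingbox")
  bounds <- NULL
  if (!inherits(bb, "xml_missing")) {
    bounds <- list(
      min = as.numeric(c(xml2::xml_attr(bb, "minx"), xml2::xml_attr(bb, "miny"),
                         xml2::xml_attr(bb, "minz"))),
      max = as.numeric(c(xml2::xml_attr(bb, "maxx"), xml2::xml_attr(bb, "maxy"),
                         xml2::xml_attr(bb, "maxz"))))
  }

  f <- skeleton_forest(skels, scale, anns, bounds)
  attr(f, "parse_log") <- list(n_things = length(skels), n_nodes = n_nodes_in,
                               n_annotations = nrow(anns),
                               unmatched_comments = unmatched)
  f
}

#' Write a skeleton forest as NML
#'
#' Emits the same dialect [read_nml()] consumes, including the voxel scale in
#' `<parameters>`, so that `read_nml(write_nml(x))` reproduces `x`
#' field-for-field. Serialization is deterministic: a fixed forest always
#' yields byte-identical output. Invariants are re-validated before writing;
#' an invalid forest is refused.
#'
#' @param forest a [skeleton_forest()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_nml <- function(forest, path) {
  for (sk in forest$skeletons) validate_skeleton(sk, warn_disconnected = FALSE)
  validate_forest_refs(forest)
  s <- unclass(forest$scale)
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<things>",
             "  <parameters>",
             sprintf("    <scale x=\"%s\" y=\"%s\" z=\"%s\"/>",
                     num_fmt(s[1]), num_fmt(s[2]), num_fmt(s[3])))
  if (!is.null(forest$bounds)) {
    b <- forest$bounds
    lines <- c(lines, sprintf(
      "    <boundingbox minx=\"%s\" miny=\"%s\" minz=\"%s\" maxx=\"%s\" maxy=\"%s\" maxz=\"%s\"/>",
      num_fmt(b$min[1]), num_fmt(b$min[2]), num_fmt(b$min[3]),
      num_fmt(b$max[1]), num_fmt(b$max[2]), num_fmt(b$max[3])))
  }
  lines <- c(lines, "  </parameters>")
  for (sk in forest$skeletons) {
    lines <- c(lines, sprintf("  <thing id=\"%d\" name=\"%s\">", sk$id,
                              xml_escape(sk$name)), "    <nodes>")
    nd <- sk$nodes
    soma <- sk$soma_node %||% NA_integer_
    cmt <- nd$comment
    cmt[!is.na(soma) & nd$node_id == soma &
          (is.na(cmt) | cmt == "")] <- "soma"
    rad <- ifelse(is.na(nd$radius), "", sprintf(" radius=\"%s\"", num_fmt(nd$radius)))
    com <- ifelse(is.na(cmt) | cmt == "", "",
                  sprintf(" comment=\"%s\"", xml_escape(cmt)))
    lines <- c(lines, sprintf("      <node id=\"%d\" x=\"%s\" y=\"%s\" z=\"%s\"%s%s/>",
                              nd$node_id, num_fmt(nd$x), num_fmt(nd$y),
                              num_fmt(nd$z), rad, com))
    lines <- c(lines, "    </nodes>", "    <edges>")
    if (nrow(sk$edges))
      lines <- c(lines, sprintf("      <edge source=\"%d\" target=\"%d\"/>",
                                sk$edges$source, sk$edges$target))
    lines <- c(lines, "    </edges>", "  </thing>")
  }
  lines <- c(lines, "</things>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
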