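# Morphology: SWC reading/writing, section building, apical region
# classification, path distances.
#
# A morphology is a rooted tree of cable sections. Sections are maximal
# unbranched runs of SWC points of one structure type; boundaries sit at
# branch points and structure-type changes. The soma (possibly multi-point
# in the SWC) is collapsed to a single equivalent cylinder: same total arc
# length, same membrane area.

.SWC_CODES <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L, other = 5L)

.structure_from_code <- function(code) {
  out <- rep("other", length(code))
  out[code == 1L] <- "soma"
  out[code == 2L] <- "axon"
  out[code == 3L] <- "basal"
  out[code == 4L] <- "apical"
  out
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC dialect (whitespace separated, `#`
#' comments, 1-based ids) and builds a validated section tree. Section
#' boundaries are placed at branch points and structure-type changes; a
#' multi-point soma is collapsed to one cylinder of equivalent arc length
#' and membrane area.
#'
#' @param path path to an SWC file
#' @return a `ca1_morphology` object: a list with a `sections` data frame
#'   (section, name, structure, parent, parent_pos, length, diam) and a
#'   `geom` list of per-section 3D point tables (x, y, z, r, arc).
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "r", "parent"),
                           colClasses = "numeric")
  if (nrow(raw) == 0L) stop("SWC format error: empty file: ", path)
  pts <- data.frame(id = as.integer(raw$id), type = as.integer(raw$type),
                    x = raw$x, y = raw$y, z = raw$z, r = raw$r,
                    parent = as.integer(raw$parent))
  validate_swc_points(pts)
  build_morphology(pts)
}

#' @noRd
validate_swc_points <- function(pts) {
  if (anyDuplicated(pts$id)) stop("SWC format error: duplicate point ids")
  if (any(pts$id <= 0L)) stop("SWC format error: non-positive point id")
  if (any(pts$r <= 0)) stop("SWC format error: non-positive radius at id ",
                            pts$id[which(pts$r <= 0)[1]])
  if (any(pts$id == pts$parent)) {
    stop("SWC structural error: cycle detected (point ", pts$id[pts$id == pts$parent][1],
         " is its own parent)")
  }
  roots <- which(pts$parent == -1L)
  if (length(roots) != 1L) stop("SWC structural error: expected exactly one root, found ",
                                length(roots))
  seen <- logical(max(pts$id))
  for (i in seq_len(nrow(pts))) {
    p <- pts$parent[i]
    if (p != -1L) {
      if (p > length(seen) || p < 1L || !seen[p]) {
        stop("SWC format error: point ", pts$id[i],
             " references parent ", p, " that is not defined earlier ",
             "(orphan or forward reference)")
      }
    }
    seen[pts$id[i]] <- TRUE
  }
  invisible(TRUE)
}

#' Build a section-tree morphology from an SWC point table
#' @param pts data.frame with id, type, x, y, z, r, parent
#' @return `ca1_morphology`
#' @keywords internal
#' @export
build_morphology <- function(pts) {
  n <- nrow(pts)
  idx_of <- integer(max(pts$id)); idx_of[pts$id] <- seq_len(n)
  parent_idx <- ifelse(pts$parent == -1L, 0L, idx_of[pmax(pts$parent, 1L)])
  nchild <- tabulate(parent_idx[parent_idx > 0L], nbins = n)
  children <- split(seq_len(n)[parent_idx > 0L], parent_idx[parent_idx > 0L])
  struct <- .structure_from_code(pts$type)
  root <- which(parent_idx == 0L)

  dist3 <- function(i, j) sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2 +
                               (pts$z[i] - pts$z[j])^2)

  is_soma <- struct == "soma"
  has_soma <- any(is_soma)

  sec_structure <- character(0); sec_parent <- integer(0)
  sec_parent_pos <- numeric(0); geom <- list()
  point_section <- integer(n)   # section owning each SWC point

  if (has_soma) {
    soma_pts <- which(is_soma)
    # arc length along parent links between soma points
    arc <- 0
    area <- 0
    for (i in soma_pts) {
      p <- parent_idx[i]
      if (p > 0L && is_soma[p]) {
        d <- dist3(i, p)
        arc <- arc + d
        area <- area + pi * (pts$r[i] + pts$r[p]) * d  # frustum lateral, slant ~ axial
      }
    }
    if (arc < 1e-9) {        # single-point (spherical) soma: L = diam = 2r
      L <- 2 * pts$r[soma_pts[1]]
      diam <- L
    } else {
      L <- arc
      diam <- area / (pi * L)
    }
    ctr <- c(mean(pts$x[soma_pts]), mean(pts$y[soma_pts]), mean(pts$z[soma_pts]))
    ax <- if (length(soma_pts) > 1L) {
      v <- c(pts$x[soma_pts[length(soma_pts)]] - pts$x[soma_pts[1]],
             pts$y[soma_pts[length(soma_pts)]] - pts$y[soma_pts[1]],
             pts$z[soma_pts[length(soma_pts)]] - pts$z[soma_pts[1]])
      if (sum(v^2) < 1e-12) c(1, 0, 0) else v / sqrt(sum(v^2))
    } else c(1, 0, 0)
    sec_structure <- "soma"; sec_parent <- 0L; sec_parent_pos <- 0
    geom[[1]] <- data.frame(
      x = c(ctr[1] - ax[1] * L / 2, ctr[1] + ax[1] * L / 2),
      y = c(ctr[2] - ax[2] * L / 2, ctr[2] + ax[2] * L / 2),
      z = c(ctr[3] - ax[3] * L / 2, ctr[3] + ax[3] * L / 2),
      r = c(diam / 2, diam / 2), arc = c(0, L))
    point_section[soma_pts] <- 1L
  }

  # a point starts a new section when its parent is absent, is soma, is a
  # branch point, or has a different structure type
  starts <- integer(0)
  for (i in seq_len(n)) {
    if (is_soma[i]) next
    p <- parent_idx[i]
    if (p == 0L || is_soma[p] || nchild[p] > 1L || struct[p] != struct[i]) {
      starts <- c(starts, i)
    }
  }

  for (s in starts) {
    p <- parent_idx[s]
    chain <- s
    cur <- s
    repeat {
      kids <- children[[as.character(cur)]]
      if (is.null(kids) || length(kids) != 1L) break
      k <- kids[1]
      if (struct[k] != struct[cur]) break
      chain <- c(chain, k); cur <- k
    }
    attach_geom <- (p > 0L && !is_soma[p])
    gi <- if (attach_geom) c(p, chain) else chain
    g <- data.frame(x = pts$x[gi], y = pts$y[gi], z = pts$z[gi], r = pts$r[gi])
    seglen <- sqrt(diff(g$x)^2 + diff(g$y)^2 + diff(g$z)^2)
    g$arc <- c(0, cumsum(seglen))
    L <- g$arc[nrow(g)]
    if (L <= 0) stop("morphology error: zero-length section starting at SWC id ",
                     pts$id[s])
    si <- length(sec_structure) + 1L
    sec_structure[si] <- struct[s]
    if (p == 0L) { sec_parent[si] <- 0L; sec_parent_pos[si] <- 0 }
    else if (is_soma[p]) { sec_parent[si] <- 1L; sec_parent_pos[si] <- 0.5 }
    else { sec_parent[si] <- point_section[p]; sec_parent_pos[si] <- 1.0 }
    geom[[si]] <- g
    point_section[chain] <- si
  }

  nsec <- length(sec_structure)
  lens <- vapply(geom, function(g) g$arc[nrow(g)], numeric(1))
  diams <- vapply(geom, function(g) {
    seglen <- diff(g$arc)
    if (sum(seglen) <= 0) return(2 * g$r[1])
    sum(seglen * (g$r[-1] + g$r[-nrow(g)])) / sum(seglen)
  }, numeric(1))
  name <- character(nsec)
  for (i in seq_len(nsec)) {
    st <- sec_structure[i]
    k <- sum(sec_structure[seq_len(i)] == st) - 1L
    name[i] <- paste0(st, "[", k, "]")
  }
  sections <- data.frame(section = seq_len(nsec), name = name,
                         structure = sec_structure, parent = sec_parent,
                         parent_pos = sec_parent_pos, length = lens,
                         diam = diams, stringsAsFactors = FALSE)
  m <- structure(list(sections = sections, geom = geom), class = "ca1_morphology")
  m$sections$dist0 <- .section_base_distances(m)
  attr(m, "point_section") <- point_section
  m
}

#' @noRd
.section_base_distances <- function(m) {
  s <- m$sections
  d0 <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    p <- s$parent[i]
    if (p == 0L) d0[i] <- 0
    else if (s$structure[p] == "soma") d0[i] <- 0
    else d0[i] <- d0[p] + s$parent_pos[i] * s$length[p]
  }
  d0
}

#' @export
print.ca1_morphology <- function(x, ...) {
  s <- x$sections
  cat("ca1_morphology:", nrow(s), "sections, total length",
      round(sum(s$length[s$structure != "soma"]), 1), "um\n")
  print(table(s$structure))
  invisible(x)
}

#' Arc-length path distance from the soma
#'
#' Distance along the tree from the soma root to a location, in micrometres.
#' The soma is the origin: any location inside the soma section is at 0.
#'
#' @param m a `ca1_morphology`
#' @param section section index
#' @param pos position along the section in `[0, 1]`
#' @return distance in um
#' @export
path_distance <- function(m, section, pos = 1.0) {
  s <- m$sections
  if (any(section < 1L | section > nrow(s))) stop("lookup error: invalid section index")
  if (any(pos < 0 | pos > 1)) stop("lookup error: position outside [0, 1]")
  out <- s$dist0[section] + pos * s$length[section]
  out[s$structure[section] == "soma"] <- 0
  out
}

#' Partition the apical tree into primary trunk, oblique, and tuft regions
#'
#' The trunk starts at the apical root and repeatedly follows the child
#' whose distal subtree has the greatest total length; it ends at the
#' terminal bifurcation, defined as the first node where the two largest
#' child subtrees each carry more than 30% of the remaining apical length.
#' Everything distal to that bifurcation is tuft; side branches shed along
#' the trunk are oblique. Non-apical sections keep their structure label.
#'
#' @param m a `ca1_morphology`
#' @return character vector of region labels per section, one of
#'   `soma`, `axon`, `basal`, `apical_primary`, `apical_oblique`,
#'   `apical_tuft`, `other`
#' @export
classify_apical_regions <- function(m) {
  s <- m$sections
  region <- s$structure
  region[region == "basal"] <- "basal"
  api <- which(s$structure == "apical")
  if (length(api) == 0L) stop("classification error: morphology has no apical sections")

  kids <- lapply(seq_len(nrow(s)), function(i) which(s$parent == i))
  subtree_len <- numeric(nrow(s))
  for (i in rev(seq_len(nrow(s)))) {        # children have larger indices
    subtree_len[i] <- s$length[i] + sum(subtree_len[kids[[i]]])
  }

  is_apical_root <- vapply(api, function(i) {
    p <- s$parent[i]
    p == 0L || s$structure[p] != "apical"
  }, logical(1))
  apical_roots <- api[is_apical_root]
  trunk_root <- apical_roots[which.max(subtree_len[apical_roots])]
  region[api] <- "apical_oblique"   # default for apical off-trunk roots

  mark_subtree <- function(i, lab) {
    stack <- i
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      region[cur] <<- lab
      stack <- c(stack, kids[[cur]])
    }
  }

  cur <- trunk_root
  repeat {
    region[cur] <- "apical_primary"
    ch <- kids[[cur]]
    ch <- ch[s$structure[ch] == "apical"]
    if (length(ch) == 0L) break                       # trunk runs to a tip
    remaining <- sum(subtree_len[ch])
    ord <- ch[order(subtree_len[ch], decreasing = TRUE)]
    if (length(ord) >= 2L &&
        subtree_len[ord[1]] > 0.3 * remaining &&
        subtree_len[ord[2]] > 0.3 * remaining) {      # terminal bifurcation
      for (k in ord) mark_subtree(k, "apical_tuft")
      break
    }
    for (k in ord[-1]) mark_subtree(k, "apical_oblique")
    cur <- ord[1]
  }
  region
}

#' Summarise a morphology as a tidy table
#'
#' @param m a `ca1_morphology`
#' @param regions optional region labels from [classify_apical_regions()]
#' @return data frame: section, name, region, length_um, mean_diam_um,
#'   path distance of the distal end
#' @export
morphology_summary <- function(m, regions = NULL) {
  s <- m$sections
  if (is.null(regions)) {
    regions <- tryCatch(classify_apical_regions(m), error = function(e) s$structure)
  }
  data.frame(section = s$section, name = s$name, region = regions,
             length_um = s$length, mean_diam_um = s$diam,
             dist_end_um = path_distance(m, s$section, 1.0),
             stringsAsFactors = FALSE)
}

#' Write a morphology to SWC
#'
#' The soma is emitted as three collinear points (centre and two ends) so
#' that its equivalent-cylinder length and area survive a round trip; each
#' other section contributes its own points, chained to the parent's
#' boundary point.
#'
#' @param m a `ca1_morphology`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_swc <- function(m, path) {
  s <- m$sections
  rows <- list()
  nextid <- 1L
  tail_id <- integer(nrow(s))   # SWC id of each section's distal boundary point
  soma_center_id <- NA_integer_

  emit <- function(type, x, y, z, r, parent) {
    rows[[length(rows) + 1L]] <<- c(nextid, type, x, y, z, r, parent)
    nextid <<- nextid + 1L
    nextid - 1L
  }

  for (i in seq_len(nrow(s))) {
    g <- m$geom[[i]]
    code <- .SWC_CODES[[if (s$structure[i] %in% names(.SWC_CODES)) s$structure[i] else "other"]]
    if (s$structure[i] == "soma") {
      ctr <- c(mean(g$x), mean(g$y), mean(g$z))
      cid <- emit(code, ctr[1], ctr[2], ctr[3], g$r[1], -1L)
      emit(code, g$x[1], g$y[1], g$z[1], g$r[1], cid)
      tid <- emit(code, g$x[2], g$y[2], g$z[2], g$r[2], cid)
      soma_center_id <- cid
      tail_id[i] <- tid
      next
    }
    p <- s$parent[i]
    if (p == 0L) {
      parent_swc <- -1L
      from <- 1L
    } else if (s$structure[p] == "soma") {
      parent_swc <- soma_center_id
      from <- 1L
    } else {
      parent_swc <- tail_id[p]
      from <- 2L   # geom row 1 duplicates the parent's boundary point
    }
    for (j in from:nrow(g)) {
      parent_swc <- emit(code, g$x[j], g$y[j], g$z[j], g$r[j], parent_swc)
    }
    tail_id[i] <- parent_swc
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by ca1sim", con)
  utils::write.table(tab, con, row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(path)
}
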