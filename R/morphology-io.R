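#' Parse an SWC reconstruction file
#'
#' Reads the 7-column SWC interchange format (`id type x y z radius parent`,
#' `#` comments, parent `-1` for roots). Soma nodes (type 1) are collapsed to
#' their centroid; every maximal subtree of non-soma nodes attached to the
#' soma (or to no parent) becomes one neurite whose first segment runs from
#' the soma centroid to its first node.
#'
#' If the file contains no soma node the centroid of the root nodes is used
#' as the soma position.
#'
#' @param path file path.
#' @param cell_id cell identifier; defaults to the file name without extension.
#' @param metadata optional named list of cell labels.
#' @return A [neuron_morphology()].
#' @export
parse_swc <- function(path, cell_id = NULL,
                      metadata = list()) {
  if (is.null(cell_id))
    cell_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("SWC parse error: no data lines in ", path)

  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop(sprintf("SWC parse error at line %d: expected 7 columns, got %d",
                 lineno[which(nf != 7L)[1]], nf[nf != 7L][1]))
  tab <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 7, byrow = TRUE)
  if (anyNA(tab)) {
    bad <- which(apply(tab, 1, anyNA))[1]
    stop(sprintf("SWC parse error at line %d: non-numeric field", lineno[bad]))
  }
  id <- as.integer(tab[, 1]); type <- as.integer(tab[, 2])
  xyz <- tab[, 3:5, drop = FALSE]; radius <- tab[, 6]
  parent <- as.integer(tab[, 7])
  if (anyDuplicated(id)) {
    bad <- which(duplicated(id))[1]
    stop(sprintf("SWC parse error at line %d: duplicate node id %d",
                 lineno[bad], id[bad]))
  }
  row_of <- seq_along(id); names(row_of) <- id
  has_parent <- parent != -1L
  unknown <- has_parent & !(parent %in% id)
  if (any(unknown)) {
    bad <- which(unknown)[1]
    stop(sprintf("SWC parse error at line %d: parent id %d is undefined",
                 lineno[bad], parent[bad]))
  }
  prow <- rep(NA_integer_, length(id))
  prow[has_parent] <- row_of[as.character(parent[has_parent])]

  is_soma <- type == 1L
  soma <- if (any(is_soma)) colMeans(xyz[is_soma, , drop = FALSE]) else NULL

  # neurite roots: non-soma nodes with no parent or a soma parent
  children <- split(seq_along(id), factor(prow, levels = seq_along(id)))
  roots <- which(!is_soma & (!has_parent | is_soma[ifelse(is.na(prow), 1L, prow)]))
  if (is.null(soma)) {
    top <- which(!has_parent)
    if (length(top) == 0L)
      stop("SWC parse error: cyclic parent chain (no root node)")
    soma <- colMeans(xyz[top, , drop = FALSE])
  }

  visited <- is_soma
  neurites <- list()
  for (r in roots) {
    ord <- integer(0)
    stack <- r
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (visited[nd])
        stop(sprintf("SWC parse error at line %d: cyclic parent chain", lineno[nd]))
      visited[nd] <- TRUE
      ord <- c(ord, nd)
      kids <- children[[nd]]
      kids <- kids[!is_soma[kids]]
      if (length(kids)) stack <- c(stack, rev(kids))
    }
    newidx <- integer(length(id)); newidx[ord] <- seq_along(ord)
    pr <- prow[ord]
    pnew <- ifelse(is.na(pr) | is_soma[ifelse(is.na(pr), 1L, pr)], 0L, newidx[pr])
    neurites[[length(neurites) + 1L]] <-
      data.frame(x = xyz[ord, 1], y = xyz[ord, 2], z = xyz[ord, 3],
                 radius = radius[ord], parent = as.integer(pnew))
  }
  if (!all(visited)) {
    bad <- which(!visited)[1]
    stop(sprintf("SWC parse error at line %d: cyclic parent chain", lineno[bad]))
  }
  neuron_morphology(cell_id, soma, neurites, metadata)
}

#' Write a morphology as SWC
#'
#' The soma centroid is written as a single type-1 node; neurite nodes are
#' written as type-3 nodes attached to it. Numeric fields use fixed 6-decimal
#' formatting so identical objects serialize byte-identically.
#'
#' @param m a [neuron_morphology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "neuron_morphology"))
  lines <- c(sprintf("# cell %s", m$cell_id),
             sprintf("1 1 %.6f %.6f %.6f 1.000000 -1",
                     m$soma[1], m$soma[2], m$soma[3]))
  nid <- 1L
  for (n in m$neurites) {
    base <- nid
    ids <- base + seq_len(nrow(n))
    par <- ifelse(n$parent == 0L, 1L, base + n$parent)
    lines <- c(lines, sprintf("%d 3 %.6f %.6f %.6f %.6f %d",
                              ids, n$x, n$y, n$z, n$radius, par))
    nid <- base + nrow(n)
  }
  writeLines(lines, path)
  invisible(path)
}

# split one neurite into unbranched chains (sections) for HOC export
neurite_sections <- function(n) {
  nk <- tabulate(n$parent[n$parent > 0L], nbins = nrow(n))
  sections <- list()
  # stack entries: c(start_node, parent_section_index)
  stack <- list(c(which(n$parent == 0L)[1], 0L))
  root_children <- which(n$parent == 0L)
  if (length(root_children) > 1L)
    stop("neurite has multiple somatic roots")  # by construction row 1 only
  kids_of <- function(i) which(n$parent == i)
  while (length(stack)) {
    e <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    chain <- e[1]
    while (nk[chain[length(chain)]] == 1L)
      chain <- c(chain, kids_of(chain[length(chain)]))
    si <- length(sections) + 1L
    sections[[si]] <- list(nodes = chain, parent = e[2])
    last <- chain[length(chain)]
    for (k in rev(kids_of(last)))
      stack[[length(stack) + 1L]] <- c(k, si)
  }
  sections
}

#' Write a morphology as Imaris-style HOC
#'
#' Emits `create`, `connect` and `pt3dadd` statements only. Each section's
#' first 3-D point repeats its attachment point (the soma centroid or the
#' parent branch node) so that section polylines carry the full geometry.
#'
#' @param m a [neuron_morphology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hoc <- function(m, path) {
  stopifnot(inherits(m, "neuron_morphology"))
  pt <- function(x, y, z, d) sprintf("  pt3dadd(%.6f, %.6f, %.6f, %.6f)", x, y, z, d)
  lines <- c(sprintf("// cell %s", m$cell_id), "create soma", "soma {",
             "  pt3dclear()",
             pt(m$soma[1], m$soma[2], m$soma[3], 2), "}")
  for (i in seq_along(m$neurites)) {
    n <- m$neurites[[i]]
    secs <- neurite_sections(n)
    nm <- sprintf("neurite%d_%d", i, seq_along(secs))
    for (j in seq_along(secs)) {
      s <- secs[[j]]
      if (s$parent == 0L) {
        attach_nm <- "soma"
        ax <- m$soma
        ar <- 1
      } else {
        attach_nm <- nm[s$parent]
        pnode <- secs[[s$parent]]$nodes
        pn <- pnode[length(pnode)]
        ax <- c(n$x[pn], n$y[pn], n$z[pn])
        ar <- n$radius[pn]
      }
      lines <- c(lines,
                 sprintf("create %s", nm[j]),
                 sprintf("connect %s(0), %s(1)", nm[j], attach_nm),
                 sprintf("%s {", nm[j]),
                 "  pt3dclear()",
                 pt(ax[1], ax[2], ax[3], 2 * ar),
                 pt(n$x[s$nodes], n$y[s$nodes], n$z[s$nodes], 2 * n$radius[s$nodes]),
                 "}")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse an Imaris-export style HOC morphology
#'
#' Honours only section creation (`create`), topology (`connect`) and 3-D
#' geometry (`pt3dadd(x, y, z, diameter)`) statements; any other HOC
#' statement is ignored with a single warning. Sections are linked into
#' neurite trees via the connect statements; the section named `soma*`
#' (or the first created section when none is) supplies the soma centroid.
#'
#' @inheritParams parse_swc
#' @return A [neuron_morphology()].
#' @export
parse_hoc <- function(path, cell_id = NULL, metadata = list()) {
  if (is.null(cell_id))
    cell_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- readLines(path, warn = FALSE)
  raw <- sub("//.*$", "", raw)

  sections <- list()   # name -> matrix of (x, y, z, radius)
  connects <- list()   # list of (child, childpos, parent, parentpos)
  current <- NULL
  depth <- 0L
  ignored <- character(0)

  for (i in seq_along(raw)) {
    line <- raw[i]
    rest <- line
    if (depth == 0L) {
      mcr <- regmatches(rest, regexec("^\\s*create\\s+(.+)$", rest))[[1]]
      if (length(mcr)) {
        for (nm in trimws(strsplit(mcr[2], ",")[[1]]))
          sections[[nm]] <- matrix(numeric(0), ncol = 4)
        next
      }
      mco <- regmatches(rest, regexec(
        "^\\s*connect\\s+(\\w+)\\s*\\(([-0-9.]+)\\)\\s*,\\s*(\\w+)\\s*\\(([-0-9.]+)\\)", rest))[[1]]
      if (length(mco)) {
        for (nm in c(mco[2], mco[4]))
          if (is.null(sections[[nm]]))
            stop(sprintf("HOC parse error at line %d: connect references undeclared section '%s'",
                         i, nm))
        connects[[length(connects) + 1L]] <-
          list(child = mco[2], childpos = as.numeric(mco[3]),
               parent = mco[4], parentpos = as.numeric(mco[5]))
        next
      }
      mop <- regmatches(rest, regexec("^\\s*(\\w+)\\s*\\{", rest))[[1]]
      if (length(mop)) {
        if (is.null(sections[[mop[2]]]))
          stop(sprintf("HOC parse error at line %d: unknown section '%s'", i, mop[2]))
        current <- mop[2]
      } else if (nzchar(trimws(rest))) {
        ignored <- c(ignored, trimws(rest))
      }
    }
    if (!is.null(current)) {
      pts <- regmatches(rest, gregexpr(
        "pt3dadd\\(\\s*([-0-9.eE]+)\\s*,\\s*([-0-9.eE]+)\\s*,\\s*([-0-9.eE]+)\\s*,\\s*([-0-9.eE]+)\\s*\\)", rest))[[1]]
      for (p in pts) {
        v <- as.numeric(strsplit(gsub("pt3dadd\\(|\\)", "", p), ",")[[1]])
        sections[[current]] <- rbind(sections[[current]],
                                     c(v[1:3], v[4] / 2))
      }
      # statements inside a block other than pt3dadd/pt3dclear are ignored
      stripped <- gsub("pt3dadd\\([^)]*\\)|pt3dclear\\(\\)", "", rest)
      stripped <- sub("^\\s*\\w+\\s*\\{", "", stripped)   # block opener
      stripped <- gsub("[{}]", "", stripped)
      if (nzchar(trimws(stripped)) && !grepl("^\\s*(create|connect)", rest))
        ignored <- c(ignored, trimws(stripped))
    }
    depth <- depth + lengths(regmatches(line, gregexpr("\\{", line))) -
      lengths(regmatches(line, gregexpr("\\}", line)))
    if (depth <= 0L) { current <- NULL; depth <- 0L }
  }
  if (length(ignored))
    warning(sprintf("parse_hoc: ignored %d non-geometry HOC statement(s), e.g. '%s'",
                    length(ignored), ignored[1]))
  if (length(sections) == 0L) stop("HOC parse error: no sections in ", path)
  empty <- names(sections)[vapply(sections, nrow, 0L) < 1L]
  if (length(empty))
    stop(sprintf("HOC parse error: section '%s' has no 3-D points", empty[1]))

  nms <- names(sections)
  soma_nm <- grep("^soma", nms, ignore.case = TRUE, value = TRUE)
  soma_nm <- if (length(soma_nm)) soma_nm[1] else nms[1]
  soma <- colMeans(sections[[soma_nm]][, 1:3, drop = FALSE])

  parent_of <- setNames(rep(NA_character_, length(nms)), nms)
  parentpos <- setNames(rep(NA_real_, length(nms)), nms)
  for (co in connects) {
    parent_of[co$child] <- co$parent
    parentpos[co$child] <- co$parentpos
  }
  kids_of <- function(nm) nms[!is.na(parent_of) & parent_of == nm]
  roots <- nms[nms != soma_nm &
                 (is.na(parent_of[nms]) | parent_of[nms] == soma_nm)]

  neurites <- list()
  for (r in roots) {
    nodes <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        radius = numeric(0), parent = integer(0))
    # stack of (section, attach_index) where attach 0 = soma
    stack <- list(list(sec = r, attach = 0L))
    while (length(stack)) {
      e <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      pts <- sections[[e$sec]]
      attach_xyz <- if (e$attach == 0L) soma else
        as.numeric(nodes[e$attach, c("x", "y", "z")])
      start <- 1L
      if (nrow(pts) > 0 && sqrt(sum((pts[1, 1:3] - attach_xyz)^2)) < 1e-9)
        start <- 2L
      idx <- seq(start, nrow(pts))
      if (start > nrow(pts)) idx <- integer(0)
      prev <- e$attach
      for (k in idx) {
        nodes <- rbind(nodes, data.frame(x = pts[k, 1], y = pts[k, 2],
                                         z = pts[k, 3], radius = pts[k, 4],
                                         parent = prev))
        prev <- nrow(nodes)
      }
      end_idx <- if (length(idx)) nrow(nodes) else e$attach
      for (k in rev(kids_of(e$sec)))
        stack[[length(stack) + 1L]] <- list(sec = k, attach = end_idx)
    }
    if (nrow(nodes) > 0L)
      neurites[[length(neurites) + 1L]] <- nodes
  }
  neuron_morphology(cell_id, soma, neurites, metadata)
}
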