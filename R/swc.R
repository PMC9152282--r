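#' Read an SWC point-diameter reconstruction
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments, whitespace separated). Radii are converted to diameters.
#' Samples are grouped into unbranched sections: a new section starts at the
#' root, wherever the parent sample has more than one child, where the sample
#' type changes, or where a sample duplicates its parent's coordinates (the
#' common convention for marking a section start). All soma samples (type 1)
#' collapse into a single root section; a single-sample soma becomes a
#' cylinder of length equal to its diameter, centered on the sample.
#'
#' @param source file path, connection, or character vector of SWC lines.
#' @return an `rxd_morphology`.
#' @export
read_swc <- function(source) {
  lines <- if (is.character(source) && length(source) == 1L && file.exists(source))
    readLines(source) else if (inherits(source, "connection"))
      readLines(source) else as.character(source)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SWC input")
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 7L)) stop("SWC parse error: expected 7 columns")
  tab <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7L,
                                 byrow = TRUE))
  if (anyNA(tab)) stop("SWC parse error: non-numeric field")
  colnames(tab) <- c("id", "type", "x", "y", "z", "r", "parent")
  id <- as.integer(tab[, "id"]); parent <- as.integer(tab[, "parent"])
  idx <- match(parent, id)
  if (any(parent != -1L & is.na(idx)))
    stop("SWC structural error: undefined parent id")
  if (sum(parent == -1L) != 1L)
    stop("SWC structural error: need exactly one root sample")
  n <- nrow(tab)
  # cycle check: every sample must reach the root
  for (i in seq_len(n)) {
    j <- i; hops <- 0L
    while (parent[j] != -1L) {
      j <- idx[j]; hops <- hops + 1L
      if (hops > n) stop("SWC structural error: cycle detected")
    }
  }
  type <- as.integer(tab[, "type"])
  nchildren <- tabulate(idx[!is.na(idx)], nbins = n)
  samp_sec <- integer(n)        # section index per sample
  secs <- list()
  soma_rows <- which(type == 1L)
  if (length(soma_rows)) {
    sp <- tab[soma_rows, c("x", "y", "z"), drop = FALSE]
    d <- 2 * tab[soma_rows, "r"]
    if (length(soma_rows) == 1L) {
      ax <- c(1, 0, 0)
      pts <- rbind(c(sp[1, ] - ax * d / 2, d), c(sp[1, ] + ax * d / 2, d))
    } else pts <- cbind(sp, d)
    secs[["soma"]] <- section("soma", pts, parent = NULL)
    samp_sec[soma_rows] <- 1L
  }
  # walk non-soma samples in id order building runs
  starts <- which(type != 1L &
                  (parent == -1L | is.na(idx) |
                   type != type[pmax(idx, 1L)] |
                   nchildren[pmax(idx, 1L)] > 1L |
                   (tab[, "x"] == tab[pmax(idx, 1L), "x"] &
                    tab[, "y"] == tab[pmax(idx, 1L), "y"] &
                    tab[, "z"] == tab[pmax(idx, 1L), "z"])))
  is_start <- rep(FALSE, n); is_start[starts] <- TRUE
  counter <- 0L
  for (i in order(id)) {
    if (type[i] == 1L) next
    if (is_start[i] || samp_sec[idx[i]] == 0L) {
      counter <- counter + 1L
      nm <- paste0("sec", counter)
      pi_ <- idx[i]
      first <- tab[i, c("x", "y", "z")]
      pts <- rbind(c(first, 2 * tab[i, "r"]))
      parent_nm <- NULL; parent_x <- 1
      if (!is.na(pi_)) {
        pcoord <- tab[pi_, c("x", "y", "z")]
        psec <- samp_sec[pi_]
        parent_nm <- names(secs)[psec]
        if (!all(pcoord == first)) {
          # prepend parent sample position (attachment point on the parent
          # centroid) with the child's first diameter
          pts <- rbind(c(pcoord, 2 * tab[i, "r"]), pts)
        }
        parent_x <- attach_fraction(secs[[parent_nm]], pcoord)
      }
      secs[[nm]] <- list(name = nm, pts = pts, parent = parent_nm,
                         parent_x = parent_x)
      samp_sec[i] <- length(secs)
    } else {
      si <- samp_sec[idx[i]]
      secs[[si]]$pts <- rbind(secs[[si]]$pts, c(tab[i, c("x", "y", "z")],
                                                2 * tab[i, "r"]))
      samp_sec[i] <- si
    }
  }
  out <- lapply(secs, function(s) {
    if (inherits(s, "rxd_section")) s else
      section(s$name, s$pts, parent = s$parent, parent_x = s$parent_x)
  })
  morphology(out)
}

attach_fraction <- function(parent_sec, coord) {
  raw <- if (!is.null(parent_sec$points)) parent_sec$points else parent_sec$pts
  pts <- raw[, 1:3, drop = FALSE]
  arcs <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  d2 <- rowSums(sweep(pts, 2, coord)^2)
  i <- which.min(d2)
  if (arcs[length(arcs)] == 0) return(1)
  arcs[i] / arcs[length(arcs)]
}

#' Write a morphology in SWC format
#'
#' Canonical formatting (`%.9g`, single spaces) so that write-read-write
#' round-trips are byte stable. The first point of a child section whose
#' coordinates coincide with its attachment sample on the parent is emitted
#' as a duplicate-coordinate sample, the convention [read_swc()] recognizes
#' as a section start.
#'
#' @param m an `rxd_morphology`.
#' @param file path or connection; if missing, the SWC lines are returned.
#' @param types named vector mapping section names to SWC type codes;
#'   defaults to 1 for a section named "soma" and 3 (basal dendrite)
#'   otherwise.
#' @return invisibly, the character vector of SWC lines.
#' @export
write_swc <- function(m, file = NULL, types = NULL) {
  stopifnot(inherits(m, "rxd_morphology"))
  lines <- character(); nid <- 0L
  last_id <- stats::setNames(vector("list", length(m$sections)), names(m$sections))
  for (nm in topo_order(m)) {
    s <- m$sections[[nm]]
    tp <- if (!is.null(types) && nm %in% names(types)) types[[nm]] else
      if (identical(nm, "soma")) 1L else 3L
    par_id <- -1L
    if (!is.null(s$parent)) {
      pids <- last_id[[s$parent]]
      # attach to the parent sample nearest the attachment fraction
      arcs <- section_arcs(m$sections[[s$parent]])
      i <- which.min(abs(arcs / arcs[length(arcs)] - s$parent_x))
      par_id <- pids[i]
    }
    ids <- integer(nrow(s$points))
    for (i in seq_len(nrow(s$points))) {
      nid <- nid + 1L
      ids[i] <- nid
      p <- s$points[i, ]
      lines <- c(lines, sprintf("%d %d %s %s %s %s %d", nid, tp,
                                fmt9(p[1]), fmt9(p[2]), fmt9(p[3]),
                                fmt9(p[4] / 2),
                                if (i == 1L) par_id else nid - 1L))
    }
    last_id[[nm]] <- ids
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

fmt9 <- function(x) sprintf("%.9g", x)
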