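#' Hybrid CT/cast airway morphometry table
#'
#' The anatomic model hybridizes two sources of airway geometry.  Airways
#' wider than 1 mm in diameter are represented explicitly with fixed mean
#' radius and length ("CT part"); below that threshold the tree is described
#' statistically, per branching order, the way silicone-cast morphometry is
#' reported ("cast part").  Each order `n` branches dichotomously into
#' daughters of orders `n - 1` and `n - 1 - delta_n`, so `delta_n` controls
#' the asymmetry of the branching pattern.
#'
#' @param ct data.frame with columns `id`, `parent` (NA for the tracheal
#'   root), `length_mm`, `radius_mm`.  Must form a rooted tree with a single
#'   root and all diameters above 1 mm.
#' @param cast data.frame with columns `order`, `len_mean`, `len_sd`,
#'   `rad_mean`, `rad_sd`, `delta_n` (all lengths in mm); one row per
#'   branching order, `delta_n >= 1`.
#' @param terminal_order Orders at or below this value are terminal
#'   bronchioles carrying a tissue unit.  Defaults to the smallest order in
#'   `cast`.
#'
#' @return An object of class `morphometry_table`.
#' @seealso [build_tree()], [read_morphometry()], [generate_morphometry_fixture()]
#' @export
morphometry_table <- function(ct, cast, terminal_order = NULL) {
  req_ct <- c("id", "parent", "length_mm", "radius_mm")
  req_cast <- c("order", "len_mean", "len_sd", "rad_mean", "rad_sd", "delta_n")
  if (!all(req_ct %in% names(ct)))
    stop("ct table needs columns: ", paste(req_ct, collapse = ", "), call. = FALSE)
  if (!all(req_cast %in% names(cast)))
    stop("cast table needs columns: ", paste(req_cast, collapse = ", "), call. = FALSE)
  ct <- as.data.frame(ct)[req_ct]
  cast <- as.data.frame(cast)[req_cast]
  ct$id <- as.character(ct$id)
  ct$parent <- as.character(ct$parent)
  if (anyDuplicated(ct$id)) stop("duplicate CT segment ids", call. = FALSE)
  root <- is.na(ct$parent)
  if (sum(root) != 1L) stop("CT table must have exactly one root", call. = FALSE)
  if (!all(ct$parent[!root] %in% ct$id))
    stop("CT parent ids must reference existing segments", call. = FALSE)
  if (any(ct$length_mm <= 0) || any(ct$radius_mm <= 0))
    stop("CT lengths and radii must be positive", call. = FALSE)
  if (any(2 * ct$radius_mm <= 1))
    stop("CT segments must exceed 1 mm in diameter; narrower airways belong in the cast table",
         call. = FALSE)
  .check_ct_acyclic(ct)
  cast$order <- as.integer(cast$order)
  if (nrow(cast) > 0L) {
    if (anyDuplicated(cast$order)) stop("duplicate cast orders", call. = FALSE)
    if (any(cast$len_mean <= 0) || any(cast$rad_mean <= 0))
      stop("cast mean lengths and radii must be positive", call. = FALSE)
    if (any(cast$len_sd < 0) || any(cast$rad_sd < 0))
      stop("cast SDs must be non-negative", call. = FALSE)
    if (any(cast$delta_n < 1))
      stop("delta_n must be >= 1", call. = FALSE)
    cast <- cast[order(cast$order), , drop = FALSE]
    terminal_order <- as.integer(terminal_order %||% min(cast$order))
    if (terminal_order < min(cast$order) || terminal_order > max(cast$order))
      stop("terminal_order must lie within the cast order range", call. = FALSE)
  } else {
    terminal_order <- NA_integer_  # CT-only table: every CT leaf is terminal
  }
  structure(list(ct = ct, cast = cast, terminal_order = terminal_order),
            class = "morphometry_table")
}

.check_ct_acyclic <- function(ct) {
  idx <- match(ct$parent, ct$id)
  for (i in seq_len(nrow(ct))) {
    seen <- integer(0)
    j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stop("CT table contains a cycle", call. = FALSE)
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  invisible(TRUE)
}

#' Read a morphometry table from CSV files
#'
#' @param ct_file CSV with columns `id,parent,length_mm,radius_mm` (empty
#'   `parent` marks the tracheal root).
#' @param cast_file CSV with columns
#'   `order,len_mean,len_sd,rad_mean,rad_sd,delta_n`.
#' @param terminal_order Passed to [morphometry_table()].
#' @return A `morphometry_table`.
#' @export
read_morphometry <- function(ct_file, cast_file, terminal_order = NULL) {
  ct <- utils::read.csv(ct_file, stringsAsFactors = FALSE)
  ct$parent[ct$parent %in% c("", "NA")] <- NA_character_
  cast <- utils::read.csv(cast_file, stringsAsFactors = FALSE)
  morphometry_table(ct, cast, terminal_order)
}

#' @export
print.morphometry_table <- function(x, ...) {
  if (nrow(x$cast) > 0L)
    cat(sprintf("<morphometry_table> CT: %d segments; cast orders %d-%d (terminal <= %d)\n",
                nrow(x$ct), min(x$cast$order), max(x$cast$order), x$terminal_order))
  else
    cat(sprintf("<morphometry_table> CT only: %d segments\n", nrow(x$ct)))
  invisible(x)
}

# Match a CT leaf to the nearest cast order by relative Euclidean distance
# in (log r, log l); ties break to the lower order.
.match_cast_order <- function(radius, length, cast) {
  d <- (log(radius) - log(cast$rad_mean))^2 + (log(length) - log(cast$len_mean))^2
  cast$order[which.min(replace(d, is.na(d), Inf))]
}

# Enumerate the full topology implied by a morphometry table, without
# sampling any geometry.  Returns parallel vectors in an order where every
# parent precedes its children (the CT table is re-sorted topologically).
# Columns: parent (index, NA for root), order (NA for CT rows), ct_row.
.enumerate_topology <- function(table) {
  ct <- table$ct
  cast <- table$cast
  t_ord <- table$terminal_order
  o_min <- if (nrow(cast) > 0L) min(cast$order) else NA_integer_
  # topological sort of the CT part
  n_ct <- nrow(ct)
  pidx <- match(ct$parent, ct$id)
  ord <- integer(0); placed <- rep(FALSE, n_ct)
  while (length(ord) < n_ct) {
    ready <- which(!placed &
                     vapply(pidx, function(p) is.na(p) || placed[p], logical(1)))
    if (length(ready) == 0L) stop("CT table is not a connected tree", call. = FALSE)
    ord <- c(ord, ready); placed[ready] <- TRUE
  }
  ct <- ct[ord, , drop = FALSE]
  pidx <- match(ct$parent, ct$id)

  # preallocated growing arrays
  cap <- 4096L
  parent <- integer(cap); order_v <- integer(cap); ct_row <- integer(cap)
  n <- n_ct
  parent[seq_len(n_ct)] <- pidx
  order_v[seq_len(n_ct)] <- NA_integer_
  ct_row[seq_len(n_ct)] <- seq_len(n_ct)

  grow <- function(min_cap) {
    while (cap < min_cap) cap <<- cap * 2L
    length(parent) <<- cap; length(order_v) <<- cap; length(ct_row) <<- cap
  }

  # stack of (parent index, order) pairs seeded from CT leaves
  is_leaf <- !(seq_len(n_ct) %in% pidx)
  stack_p <- integer(0); stack_o <- integer(0)
  if (nrow(cast) > 0L) for (i in which(is_leaf)) {
    o <- .match_cast_order(ct$radius_mm[i], ct$length_mm[i], cast)
    if (o <= t_ord) next  # CT leaf already terminal-scale: no cast subtree
    dn <- cast$delta_n[match(o, cast$order)]
    kids <- pmax(c(o - 1L, o - 1L - dn), o_min)
    stack_p <- c(stack_p, i, i); stack_o <- c(stack_o, kids)
  }
  max_nodes <- 5e6
  while (length(stack_p) > 0L) {
    p <- stack_p[length(stack_p)]; o <- stack_o[length(stack_o)]
    stack_p <- stack_p[-length(stack_p)]; stack_o <- stack_o[-length(stack_o)]
    n <- n + 1L
    if (n > cap) grow(n)
    if (n > max_nodes) stop("airway tree recursion exceeds guard size; check delta_n", call. = FALSE)
    parent[n] <- p; order_v[n] <- o; ct_row[n] <- NA_integer_
    if (o > t_ord) {
      dn <- cast$delta_n[match(o, cast$order)]
      if (is.na(dn)) stop(sprintf("no cast row for order %d", o), call. = FALSE)
      kids <- pmax(c(o - 1L, o - 1L - dn), o_min)
      stack_p <- c(stack_p, n, n); stack_o <- c(stack_o, kids)
    }
  }
  list(parent = parent[seq_len(n)], order = order_v[seq_len(n)],
       ct_row = ct_row[seq_len(n)], n_ct = n_ct, ct = ct)
}

#' Build a stochastic airway tree
#'
#' Reproduces the CT part of the morphometry verbatim, then grows a
#' dichotomous cast-order subtree beneath every CT leaf: order `n` branches
#' into orders `n - 1` and `n - 1 - delta_n` until the terminal order is
#' reached.  Per-segment radius and length are drawn from the order's
#' mean/SD via a truncated normal (lower truncation at 10\% of the mean, so
#' geometry stays positive and near the cast measurements).  The same seed
#' always yields the identical tree.
#'
#' @param table A [morphometry_table()].
#' @param seed Integer seed controlling geometry sampling; `NULL` uses the
#'   current RNG stream.
#' @return An object of class `airway_tree`: a list with `segments` (a
#'   data.frame with one row per airway: `parent` index, `order`, `radius`,
#'   `length` in mm, `volume` in mL, `terminal` flag, `source`),
#'   `n_terminal`, `seed`, and the cumulative `radial_scale` applied.
#' @examples
#' tab <- generate_morphometry_fixture()
#' tree <- build_tree(tab, seed = 1)
#' tree
#' @export
build_tree <- function(table, seed = NULL) {
  stopifnot(inherits(table, "morphometry_table"))
  topo <- .enumerate_topology(table)
  n <- length(topo$parent)
  radius <- numeric(n); len <- numeric(n)
  ctr <- topo$ct_row
  is_ct <- !is.na(ctr)
  radius[is_ct] <- topo$ct$radius_mm[ctr[is_ct]]
  len[is_ct] <- topo$ct$length_mm[ctr[is_ct]]
  cast <- table$cast
  oi <- match(topo$order, cast$order)
  local_seed(seed, {
    k <- which(!is_ct)
    radius[k] <- rnorm_truncated(length(k), cast$rad_mean[oi[k]],
                                 cast$rad_sd[oi[k]], 0.1 * cast$rad_mean[oi[k]])
    len[k] <- rnorm_truncated(length(k), cast$len_mean[oi[k]],
                              cast$len_sd[oi[k]], 0.1 * cast$len_mean[oi[k]])
  })
  has_child <- seq_len(n) %in% topo$parent
  terminal <- !has_child
  segments <- data.frame(
    parent = topo$parent, order = topo$order,
    radius = radius, length = len,
    volume = pi * radius^2 * len / 1000,  # mm^3 -> mL
    terminal = terminal,
    source = ifelse(is_ct, "ct", "cast"),
    stringsAsFactors = FALSE)
  structure(list(segments = segments,
                 n_terminal = sum(terminal),
                 seed = seed,
                 radial_scale = 1),
            class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  cat(sprintf("<airway_tree> %d segments (%d terminal), total volume %.4g mL, r/r0 = %g\n",
              nrow(x$segments), x$n_terminal, total_tree_volume(x), x$radial_scale))
  invisible(x)
}

#' Total airway tree volume
#'
#' Sums per-segment volumes `V_seg = pi r^2 l` by the recursive traversal
#' `V_n = V_seg(n) + V_(n-1) + V_(n-1-delta_n)`, evaluated bottom-up from
#' the terminal bronchioles to the trachea (every segment is visited exactly
#' once, so the result equals the flat sum of segment volumes).
#'
#' @param tree An `airway_tree`.
#' @return Total volume in mL.
#' @export
total_tree_volume <- function(tree) {
  stopifnot(inherits(tree, "airway_tree"))
  seg <- tree$segments
  n <- nrow(seg)
  acc <- seg$volume
  for (i in n:1) {        # parents precede children, so reverse order is postorder
    p <- seg$parent[i]
    if (!is.na(p)) acc[p] <- acc[p] + acc[i]
  }
  acc[which(is.na(seg$parent))]
}

#' Apply a uniform radial scale factor to an airway tree
#'
#' Airway geometry is measured at total lung capacity; at lower distending
#' pressures every radius is contracted by a common factor `r/r0` in (0, 1].
#' Lengths are unchanged and segment volumes are recomputed.
#'
#' @param tree An `airway_tree`.
#' @param r_over_r0 Scale factor in (0, 1], applied to the tree's *current*
#'   radii.
#' @return The rescaled `airway_tree`; its `radial_scale` field accumulates
#'   the factors applied so far.
#' @export
apply_radial_scale <- function(tree, r_over_r0) {
  stopifnot(inherits(tree, "airway_tree"))
  stopifnot_scalar(r_over_r0, "r_over_r0")
  if (r_over_r0 <= 0 || r_over_r0 > 1)
    stop("r_over_r0 must lie in (0, 1]", call. = FALSE)
  tree$segments$radius <- tree$segments$radius * r_over_r0
  tree$segments$volume <- pi * tree$segments$radius^2 * tree$segments$length / 1000
  tree$radial_scale <- tree$radial_scale * r_over_r0
  tree
}
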