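# Morphology: the granule-cell section tree and its compartmental grid.
#
# A morphology is a list with
#   sections: data.frame(id, kind, length, diam_prox, diam_dist,
#                        parent_id, parent_pos, nseg)
#   passive:  list(cm_uf_cm2, rm_kohm_cm2, ri_ohm_cm, e_leak_mv, v_rest_mv)
# Sections are stored parent-before-child; the single root (parent_id NA) is
# the soma.  All sections are uniform cylinders except the first axonal
# cylinder, which tapers linearly (a frustum).

new_section <- function(id, kind, length, diam_prox, diam_dist = diam_prox,
                        parent_id = NA_character_, parent_pos = 1.0) {
  if (length <= 0 || diam_prox <= 0 || diam_dist <= 0) {
    stop("configuration error: section '", id,
         "' has non-positive length or diameter")
  }
  data.frame(id = id, kind = kind, length = length,
             diam_prox = diam_prox, diam_dist = diam_dist,
             parent_id = parent_id, parent_pos = parent_pos,
             stringsAsFactors = FALSE)
}

#' Build the granule-cell model tree
#'
#' Constructs the branched section tree of the dentate granule cell: a soma
#' (15 um cylinder), a dendritic arborization (one main trunk carrying three
#' primary and nine secondary branches), ten 150-um axonal cylinders of 0.4 um
#' diameter (the first tapering from 1 to 0.4 um) with ten en-passant mossy
#' fiber boutons (7 um) in series, four 20 x 0.1 um filopodial extensions per
#' bouton, and hilar collaterals (200 x 0.2 um) originating 50, 100 and 200 um
#' down the axon, each ending in one large bouton.
#'
#' @param params geometry parameter list (`default_params()$geometry`);
#'   individual entries may be overridden.
#' @param passive passive membrane parameters (`default_params()$passive`).
#' @return an object of class `mf_morphology`.
#' @export
#' @examples
#' m <- build_granule_cell()
#' subset(m$sections, kind == "collateral")
build_granule_cell <- function(params = default_params()$geometry,
                               passive = default_params()$passive) {
  g <- params
  secs <- list(new_section("soma", "soma", g$soma$length, g$soma$diam,
                           parent_id = NA_character_, parent_pos = NA_real_))
  add <- function(s) secs[[length(secs) + 1L]] <<- s

  # dendrites: trunk at the 0-end of the soma, opposite the axon
  add(new_section("dend_trunk", "dendrite_trunk", g$dend_trunk$length,
                  g$dend_trunk$diam, parent_id = "soma", parent_pos = 0))
  n_sec <- 0L
  for (p in seq_len(g$dend_primary$count)) {
    add(new_section(paste0("dend_primary_", p), "dendrite_primary",
                    g$dend_primary$length, g$dend_primary$diam,
                    parent_id = "dend_trunk", parent_pos = 1))
    for (s in seq_len(g$dend_secondary$per_primary)) {
      n_sec <- n_sec + 1L
      add(new_section(paste0("dend_secondary_", n_sec), "dendrite_secondary",
                      g$dend_secondary$length, g$dend_secondary$diam,
                      parent_id = paste0("dend_primary_", p), parent_pos = 1))
    }
  }

  # main axon: cylinders and en-passant boutons in series
  ncyl <- g$axon$n_cylinders
  for (k in seq_len(ncyl)) {
    dp <- if (k == 1L) g$axon$first_diam_prox else g$axon$diam
    par <- if (k == 1L) "soma" else paste0("bouton_", k - 1L)
    add(new_section(paste0("axon_", k), "axon", g$axon$length_per_cylinder,
                    dp, g$axon$diam, parent_id = par, parent_pos = 1))
    add(new_section(paste0("bouton_", k), "bouton", g$bouton$length,
                    g$bouton$diam, parent_id = paste0("axon_", k),
                    parent_pos = 1))
    for (f in seq_len(g$filopodium$per_bouton)) {
      add(new_section(paste0("filo_", k, "_", f), "filopodium",
                      g$filopodium$length, g$filopodium$diam,
                      parent_id = paste0("bouton_", k), parent_pos = 0.5))
    }
  }

  # hilar collaterals: origin measured as arc distance along the axon from
  # the soma-axon junction (boutons included en route)
  origins <- g$collateral$origins_um
  if (length(origins)) {
    span <- ncyl * (g$axon$length_per_cylinder + g$bouton$length)
    for (i in seq_along(origins)) {
      d <- origins[i]
      if (d >= span) {
        stop("configuration error: collateral origin ", d,
             " um lies beyond the axon")
      }
      loc <- axon_arc_locate(d, g$axon$length_per_cylinder, g$bouton$length)
      add(new_section(paste0("collateral_", i), "collateral",
                      g$collateral$length, g$collateral$diam,
                      parent_id = loc$id, parent_pos = loc$pos))
      add(new_section(paste0("collateral_bouton_", i), "collateral_bouton",
                      g$collateral$bouton_length, g$collateral$bouton_diam,
                      parent_id = paste0("collateral_", i), parent_pos = 1))
    }
  }

  sections <- do.call(rbind, secs)
  rownames(sections) <- NULL
  m <- structure(list(sections = sections, passive = passive),
                 class = "mf_morphology")
  validate_morphology(m)
  m
}

# locate the (section, relative position) lying `d` um along the axon from
# the soma-axon junction
axon_arc_locate <- function(d, cyl_len, bouton_len) {
  x <- 0
  k <- 0L
  repeat {
    k <- k + 1L
    if (d <= x + cyl_len) {
      return(list(id = paste0("axon_", k), pos = (d - x) / cyl_len))
    }
    x <- x + cyl_len
    if (d <= x + bouton_len) {
      return(list(id = paste0("bouton_", k), pos = (d - x) / bouton_len))
    }
    x <- x + bouton_len
  }
}

validate_morphology <- function(m) {
  s <- m$sections
  if (anyDuplicated(s$id)) stop("duplicate section ids")
  root <- which(is.na(s$parent_id))
  if (length(root) != 1L) stop("morphology must have exactly one root")
  idx <- match(s$parent_id, s$id)
  bad <- which(!is.na(s$parent_id) & (is.na(idx) | idx >= seq_len(nrow(s))))
  if (length(bad)) {
    stop("parent of section '", s$id[bad[1]],
         "' not defined before it (tree must be parent-ordered)")
  }
  if (any(s$length <= 0) || any(s$diam_prox <= 0) || any(s$diam_dist <= 0)) {
    stop("configuration error: non-positive length or diameter")
  }
  invisible(m)
}

#' @export
print.mf_morphology <- function(x, ...) {
  s <- x$sections
  cat("<mf_morphology> ", nrow(s), " sections, total area ",
      format(sum(section_area_um2(s)), digits = 6), " um^2\n", sep = "")
  print(table(s$kind))
  invisible(x)
}

# lateral (frustum) surface area of each section, um^2
section_area_um2 <- function(s) {
  slant <- sqrt(s$length^2 + ((s$diam_prox - s$diam_dist) / 2)^2)
  pi * (s$diam_prox + s$diam_dist) / 2 * slant
}

#' Section ids usable as landmarks
#'
#' Any section id is a landmark; a landmark refers to the section midpoint.
#' @param m an `mf_morphology` or `mf_grid`.
#' @return character vector of landmark names.
#' @export
landmarks <- function(m) {
  if (inherits(m, "mf_grid")) m$sections$id else m$sections$id
}

# ---- path distances -------------------------------------------------------

# chain of (section index, arc position um within that section) from a point
# up to the root; returns list(sec_idx, entry_um, dist) where entry_um[k] is
# the arc position in ancestor k at which the path enters it, and dist[k] the
# path length from the point to that entry.
.ancestor_chain <- function(s, sec_i, pos_um) {
  sec_idx <- integer(0); entry_um <- numeric(0); dist <- numeric(0)
  i <- sec_i; x <- pos_um; d <- 0
  repeat {
    sec_idx <- c(sec_idx, i); entry_um <- c(entry_um, x); dist <- c(dist, d)
    pid <- s$parent_id[i]
    if (is.na(pid)) break
    d <- d + x                      # walk to the section's 0-end
    p <- match(pid, s$id)
    x <- s$parent_pos[i] * s$length[p]
    i <- p
  }
  list(sec_idx = sec_idx, entry_um = entry_um, dist = dist)
}

#' Path distance between two landmarks
#'
#' Arc length along the unique tree path between the midpoints of two named
#' sections (e.g. `"soma"` to `"bouton_1"`).
#'
#' @param m an `mf_morphology`.
#' @param a,b landmark names (section ids), or a list `list(id =, pos =)` with
#'   `pos` a relative position in `[0, 1]`.
#' @return distance in um.
#' @export
#' @examples
#' m <- build_granule_cell()
#' path_distance(m, "soma", "bouton_1")
path_distance <- function(m, a, b) {
  s <- m$sections
  pt <- function(x) {
    if (is.list(x)) {
      i <- match(x$id, s$id)
      if (is.na(i)) stop("lookup error: unknown landmark '", x$id, "'")
      list(i = i, pos = x$pos * s$length[i])
    } else {
      i <- match(x, s$id)
      if (is.na(i)) stop("lookup error: unknown landmark '", x, "'")
      list(i = i, pos = 0.5 * s$length[i])
    }
  }
  pa <- pt(a); pb <- pt(b)
  ca <- .ancestor_chain(s, pa$i, pa$pos)
  cb <- .ancestor_chain(s, pb$i, pb$pos)
  # deepest common ancestor section shared by both chains
  common <- intersect(ca$sec_idx, cb$sec_idx)
  lca <- common[1]                  # chains are ordered leaf -> root
  ia <- match(lca, ca$sec_idx); ib <- match(lca, cb$sec_idx)
  ca$dist[ia] + cb$dist[ib] + abs(ca$entry_um[ia] - cb$entry_um[ib])
}

# ---- discretization -------------------------------------------------------

#' Discretization rule
#'
#' @param max_seg_um maximum segment length; every section gets an odd number
#'   of segments of at most this length (>= 1 segment).
#' @return a list usable as the `rule` argument of [discretize()].
#' @export
discretization_rule <- function(max_seg_um = 10) {
  if (max_seg_um <= 0) stop("invalid rule: max_seg_um must be positive")
  list(max_seg_um = max_seg_um)
}

# frustum axial resistance over [xa, xb] of a section (um, Ohm)
.frustum_res <- function(ri_ohm_cm, xa, xb, L, d0, d1) {
  da <- d0 + (d1 - d0) * xa / L
  db <- d0 + (d1 - d0) * xb / L
  4 * ri_ohm_cm * ((xb - xa) * 1e-4) / (pi * (da * 1e-4) * (db * 1e-4))
}

# frustum lateral area over [xa, xb], um^2
.frustum_area <- function(xa, xb, L, d0, d1) {
  da <- d0 + (d1 - d0) * xa / L
  db <- d0 + (d1 - d0) * xb / L
  slant <- sqrt((xb - xa)^2 + ((da - db) / 2)^2)
  pi * (da + db) / 2 * slant
}

#' Discretize a morphology into a compartment grid
#'
#' Splits every section into an odd number of segments no longer than the
#' rule's `max_seg_um`, computes per-compartment membrane areas (frustum
#' lateral surface) and axial conductances (frustum resistance between
#' adjacent compartment centers; a child section couples to the parent
#' compartment containing its attachment point through its own proximal half
#' resistance).
#'
#' @param m an `mf_morphology`.
#' @param rule see [discretization_rule()].
#' @return an object of class `mf_grid`: list with `comp` (data.frame of
#'   compartments), `sections`, `passive`.
#' @export
discretize <- function(m, rule = discretization_rule()) {
  s <- m$sections
  ri <- m$passive$ri_ohm_cm
  nsec <- nrow(s)
  nseg <- pmax(1L, ceiling(s$length / rule$max_seg_um))
  nseg <- ifelse(nseg %% 2L == 0L, nseg + 1L, nseg)

  first_comp <- integer(nsec)       # 1-based index of first comp per section
  total <- sum(nseg)
  sec_of <- integer(total); seg_of <- integer(total)
  x0 <- numeric(total); x1 <- numeric(total); xc <- numeric(total)
  area <- numeric(total); parent <- integer(total); ga <- numeric(total)

  k <- 0L
  for (i in seq_len(nsec)) {
    first_comp[i] <- k + 1L
    L <- s$length[i]; n <- nseg[i]
    dx <- L / n
    for (j in seq_len(n)) {
      k <- k + 1L
      sec_of[k] <- i; seg_of[k] <- j
      x0[k] <- (j - 1) * dx; x1[k] <- j * dx; xc[k] <- (j - 0.5) * dx
      area[k] <- .frustum_area(x0[k], x1[k], L, s$diam_prox[i], s$diam_dist[i])
      if (j > 1L) {
        parent[k] <- k - 1L
        r <- .frustum_res(ri, xc[k - 1L], xc[k], L,
                          s$diam_prox[i], s$diam_dist[i])
        ga[k] <- 1e6 / r
      } else if (is.na(s$parent_id[i])) {
        parent[k] <- NA_integer_; ga[k] <- 0
      } else {
        pi_ <- match(s$parent_id[i], s$id)
        ppos <- s$parent_pos[i] * s$length[pi_]
        pseg <- min(nseg[pi_], max(1L, ceiling(ppos / (s$length[pi_] / nseg[pi_]))))
        parent[k] <- first_comp[pi_] + pseg - 1L
        r <- .frustum_res(ri, 0, xc[k], L, s$diam_prox[i], s$diam_dist[i])
        ga[k] <- 1e6 / r
      }
    }
  }

  comp <- data.frame(section = s$id[sec_of], kind = s$kind[sec_of],
                     seg = seg_of, x0 = x0, x1 = x1, xc = xc,
                     area_cm2 = area * 1e-8, parent = parent, ga_us = ga,
                     stringsAsFactors = FALSE)
  g <- structure(list(comp = comp, sections = s, passive = m$passive,
                      first_comp = setNames(first_comp, s$id),
                      nseg = setNames(nseg, s$id), morphology = m),
                 class = "mf_grid")
  root_id <- s$id[is.na(s$parent_id)]
  g$comp$path_um <- vapply(seq_len(nrow(comp)), function(i) {
    path_distance(m, root_id,
                  list(id = comp$section[i], pos = comp$xc[i] / s$length[sec_of[i]]))
  }, numeric(1))
  g
}

#' @export
print.mf_grid <- function(x, ...) {
  cat("<mf_grid> ", nrow(x$comp), " compartments over ",
      nrow(x$sections), " sections; total area ",
      format(sum(x$comp$area_cm2) * 1e8, digits = 6), " um^2\n", sep = "")
  invisible(x)
}

# compartment index (1-based) of a landmark point
landmark_comp <- function(grid, landmark, pos = 0.5) {
  s <- grid$sections
  i <- match(landmark, s$id)
  if (is.na(i)) stop("lookup error: unknown landmark '", landmark, "'")
  x <- pos * s$length[i]
  sel <- which(grid$comp$section == landmark)
  sel[findInterval(x, grid$comp$x0[sel], rightmost.closed = TRUE)]
}

# ---- simple builders used by tests and clamp protocols --------------------

#' Single-section cylinder morphology
#'
#' @param diam,length cylinder dimensions, um.
#' @param passive passive parameters.
#' @return `mf_morphology` with one section `"cable"`.
#' @export
cylinder_morphology <- function(diam, length,
                                passive = default_params()$passive) {
  sec <- new_section("cable", "axon", length, diam,
                     parent_id = NA_character_, parent_pos = NA_real_)
  structure(list(sections = sec, passive = passive), class = "mf_morphology")
}

#' Single-compartment sphere (by membrane area)
#'
#' A cylinder with equal diameter and length has the same lateral area as a
#' sphere of that diameter; used for single-compartment voltage clamp.
#' @param diam sphere diameter, um.
#' @param passive passive parameters.
#' @return `mf_grid` with exactly one compartment.
#' @export
sphere_grid <- function(diam = 10, passive = default_params()$passive) {
  m <- cylinder_morphology(diam, diam, passive)
  m$sections$kind <- "soma"
  m$sections$id <- "sphere"
  discretize(m, discretization_rule(max_seg_um = diam))
}
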