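# Orchestration of the muscle decomposition pipeline: attachment projection
# and removal, field solve, contour stack, template mapping, attachment
# connection, and fibre smoothing.

#' Attachment area
#'
#' An origin or insertion area, described as an ordered closed outline of
#' landmarks fixed on a bone.
#'
#' @param name `"origin"` or `"insertion"`.
#' @param bone bone identifier the landmarks are fixed on.
#' @param landmarks n x 3 matrix (n >= 3) of ordered outline points (m).
#' @return an object of class `attachment_area` with a derived `centroid`.
#' @export
attachment_area <- function(name, bone, landmarks) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) < 3L) stopf("attachment '%s' needs >= 3 landmarks", name)
  if (ncol(landmarks) != 3L) stopf("landmarks must be n x 3")
  structure(list(name = name, bone = bone, landmarks = landmarks,
                 centroid = colMeans(landmarks)),
            class = "attachment_area")
}

#' Read attachment areas from a landmark JSON file
#'
#' The file holds `{"units": "...", "landmarks": [{"name", "bone",
#' "position"}, ...]}`; landmarks named `origin*` / `insertion*` are grouped
#' into the two areas in file order.
#'
#' @param path JSON file path.
#' @return named list with `origin` and `insertion` [attachment_area()]s.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  scale <- unit_scale(doc$units %||% "m")
  lms <- doc$landmarks
  pick <- function(prefix) {
    sel <- Filter(function(l) startsWith(l$name, prefix), lms)
    if (!length(sel)) stopf("no '%s*' landmarks in %s", prefix, path)
    pos <- do.call(rbind, lapply(sel, function(l) unlist(l$position))) * scale
    attachment_area(prefix, sel[[1L]]$bone, pos)
  }
  list(origin = pick("origin"), insertion = pick("insertion"))
}

#' Write attachment areas to a landmark JSON file
#'
#' @param areas list with `origin` and `insertion` [attachment_area()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(areas, path) {
  lms <- list()
  for (area in areas) {
    for (i in seq_len(nrow(area$landmarks))) {
      lms[[length(lms) + 1L]] <- list(
        name = sprintf("%s_%02d", area$name, i),
        bone = area$bone,
        position = as.numeric(area$landmarks[i, ]))
    }
  }
  jsonlite::write_json(list(units = "m", landmarks = lms), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Project an attachment area onto the muscle mesh
#'
#' Each landmark is projected to its closest point on the muscle surface and
#' snapped to the nearest mesh vertex; consecutive projected landmarks are
#' connected by shortest edge paths, outlining a closed loop whose enclosed
#' faces form the attachment region.
#'
#' @param muscle a closed (or nearly closed) [trimesh()].
#' @param area an [attachment_area()].
#' @param capture maximum landmark-to-surface distance (m, default 0.02).
#' @return list of class `surface_region` with `faces` (face indices),
#'   `outline` (vertex-index loop) and `area_name`.
#' @export
project_attachment <- function(muscle, area, capture = 0.02) {
  lm <- area$landmarks
  proj <- closest_point_on_mesh(lm, muscle)
  too_far <- proj$distance > capture
  if (any(too_far)) {
    stopf("attachment '%s': landmark %d is %.4f m from the mesh (capture %.4f m)",
          area$name, which(too_far)[1L], proj$distance[which(too_far)[1L]],
          capture)
  }
  # snap to nearest vertices
  vidx <- vapply(seq_len(nrow(lm)), function(i) {
    which.min(row_norms(sweep(muscle$vertices, 2L, proj$point[i, ])))
  }, 0L)
  vidx <- vidx[!duplicated(vidx)]
  if (length(vidx) < 3L) {
    stopf("attachment '%s' collapses to fewer than 3 mesh vertices", area$name)
  }

  g <- mesh_edge_graph(muscle)
  outline <- integer(0)
  for (i in seq_along(vidx)) {
    a <- vidx[i]
    b <- vidx[if (i == length(vidx)) 1L else i + 1L]
    sp <- igraph::shortest_paths(g, from = a, to = b, mode = "all")$vpath[[1L]]
    sp <- as.integer(sp)
    outline <- c(outline, sp[-length(sp)])
  }
  outline <- outline[!duplicated(outline)]

  # cut dual face-adjacency along outline edges; region = component nearest
  # the landmark centroid
  faces <- region_inside_outline(muscle, outline, area$centroid)
  if (length(faces) == 0L) {
    stopf("attachment '%s': no enclosed faces found", area$name)
  }
  structure(list(faces = faces, outline = outline, area_name = area$name),
            class = "surface_region")
}

mesh_edge_graph <- function(mesh) {
  e <- unique_edges(mesh$faces)
  w <- row_norms(mesh$vertices[e[, 1L], , drop = FALSE] -
                   mesh$vertices[e[, 2L], , drop = FALSE])
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

# Faces enclosed by a closed vertex outline: remove dual edges whose shared
# mesh edge has both endpoints on the outline, then take the connected
# component containing the face closest to `target`.
region_inside_outline <- function(mesh, outline, target) {
  f <- mesh$faces
  nf <- nrow(f)
  keys <- edge_keys(face_edges(f))
  face_of <- rep(seq_len(nf), 3L)
  e <- face_edges(f)
  cut <- outline_edge_set(outline)
  blocked <- edge_keys(e) %in% cut
  keep <- !blocked
  # dual adjacency through non-blocked shared edges
  split_faces <- split(face_of[keep], keys[keep])
  pairs <- Filter(function(x) length(x) == 2L, split_faces)
  if (length(pairs)) {
    el <- do.call(rbind, pairs)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nf - igraph::vcount(g)))
  } else {
    g <- igraph::make_empty_graph(n = nf, directed = FALSE)
  }
  comp <- igraph::components(g)$membership
  cent <- face_centroids(mesh)
  seed <- which.min(row_norms(sweep(cent, 2L, target)))
  which(comp == comp[seed])
}

# Split a face-index set into connected components (shared-edge adjacency).
region_components <- function(all_faces, faces) {
  sub <- all_faces[faces, , drop = FALSE]
  keys <- edge_keys(face_edges(sub))
  face_of <- rep(seq_len(nrow(sub)), 3L)
  pairs <- Filter(function(x) length(x) == 2L, split(face_of, keys))
  g <- if (length(pairs)) {
    igraph::graph_from_edgelist(do.call(rbind, pairs), directed = FALSE)
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  g <- igraph::add_vertices(g, max(0L, nrow(sub) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  lapply(split(seq_len(nrow(sub)), memb), function(i) faces[i])
}

# Undirected edge keys of consecutive outline vertices.
outline_edge_set <- function(outline) {
  nxt <- c(outline[-1L], outline[1L])
  paste(pmin(outline, nxt), pmax(outline, nxt), sep = "-")
}

#' Remove a surface region from a mesh
#'
#' Removes the region's faces, leaving one new boundary loop.  The region
#' must be simply connected (a topological disk) and its removal must not
#' disconnect the mesh.
#'
#' @param muscle a [trimesh()].
#' @param region a `surface_region` from [project_attachment()] (or an
#'   integer vector of face indices).
#' @return an open [trimesh()].
#' @export
remove_region <- function(muscle, region) {
  faces <- if (inherits(region, "surface_region")) region$faces else region
  if (length(faces) == 0L) stopf("remove_region: empty region")
  # every connected component of the region must be a topological disk
  for (comp_faces in region_components(muscle$faces, faces)) {
    sub <- muscle$faces[comp_faces, , drop = FALSE]
    vsub <- length(unique(as.vector(sub)))
    esub <- length(unique(edge_keys(face_edges(sub))))
    chi <- vsub - esub + nrow(sub)
    if (chi != 1L) {
      stopf("remove_region: region is not simply connected (Euler characteristic %d)",
            chi)
    }
  }
  rest <- muscle$faces[-faces, , drop = FALSE]
  if (nrow(rest) == 0L) stopf("remove_region: nothing left after removal")
  used <- sort(unique(as.vector(rest)))
  remap <- integer(n_vertices(muscle))
  remap[used] <- seq_along(used)
  out <- trimesh(muscle$vertices[used, , drop = FALSE],
                 matrix(remap[rest], ncol = 3L), name = muscle$name)
  # connectivity check on the face graph
  comp <- igraph::components(mesh_edge_graph(out))
  if (comp$no > 1L) stopf("remove_region: removal disconnects the mesh")
  out
}

#' Set of polyline fibres decomposing a muscle
#'
#' @param points `n_fibers x n_points x 3` array of ordered fibre points (m),
#'   origin to insertion.
#' @param muscle muscle identifier.
#' @param bindings optional kinematic bindings (filled by [assign_bones()]).
#' @return object of class `fiber_set`.
#' @export
fiber_set <- function(points, muscle = "muscle", bindings = NULL) {
  stopifnot(length(dim(points)) == 3L, dim(points)[3L] == 3L)
  if (any(!is.finite(points))) stopf("fiber_set: non-finite coordinates")
  structure(list(points = points, n_fibers = dim(points)[1L],
                 n_points = dim(points)[2L], muscle = muscle,
                 bindings = bindings),
            class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("<fiber_set '%s': %d fibres x %d points (%d segments)%s>\n",
              x$muscle, x$n_fibers, x$n_points, x$n_points - 1L,
              if (is.null(x$bindings)) "" else ", bound"))
  invisible(x)
}

#' Per-fibre polyline lengths
#'
#' @param fibers a `fiber_set`.
#' @return numeric vector of fibre lengths (m).
#' @export
fiber_lengths <- function(fibers) {
  p <- fibers$points
  segs <- p[, -1L, , drop = FALSE] - p[, -dim(p)[2L], , drop = FALSE]
  rowSums(sqrt(apply(segs^2, c(1L, 2L), sum)))
}

#' Decompose a muscle surface mesh into polyline fibres
#'
#' Full pipeline: both attachment areas are projected onto the muscle mesh
#' and their regions removed; the harmonic field is solved between the two
#' resulting boundaries; `n_segments - 1` interior contours are extracted at
#' levels `k / n_segments`; the template is sliced at the same levels and
#' each section mapped onto its contour with mean-value coordinates; finally
#' fibre endpoints are attached to the attachment outlines and the fibres
#' smoothed.  Each fibre has `n_segments + 1` points.  Deterministic.
#'
#' @param muscle a closed [trimesh()].
#' @param origin,insertion [attachment_area()]s.
#' @param n_fibers number of fibres (>= 1).
#' @param n_segments straight-line segments per fibre (>= 2).
#' @param template optional `fiber_template` (default: parallel template).
#' @param lam fibre smoothing penalty (default 1).
#' @param n_samples contour resampling count (default 64).
#' @param capture landmark capture distance (m).
#' @return a `fiber_set`.
#' @export
decompose_muscle <- function(muscle, origin, insertion, n_fibers = 100L,
                             n_segments = 15L, template = NULL, lam = 1,
                             n_samples = 64L, capture = 0.02) {
  if (n_fibers < 1L) stopf("n_fibers must be >= 1")
  if (n_segments < 2L) stopf("n_segments must be >= 2")
  template <- template %||% make_parallel_template(n_fibers)
  if (template$n_fibers != n_fibers) {
    stopf("template has %d fibres but n_fibers = %d", template$n_fibers,
          n_fibers)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stopf("decompose_muscle failed at stage '%s': %s", what,
            conditionMessage(e))
    })
  }

  reg_o <- stage("project origin", project_attachment(muscle, origin, capture))
  reg_i <- stage("project insertion",
                 project_attachment(muscle, insertion, capture))
  if (length(intersect(reg_o$faces, reg_i$faces))) {
    stopf("origin and insertion regions overlap on the muscle mesh")
  }
  open_mesh <- stage("remove attachments",
                     remove_region(muscle, sort(c(reg_o$faces, reg_i$faces))))

  loops <- stage("boundary extraction", boundary_loops(open_mesh))
  if (length(loops) != 2L) {
    stopf("expected 2 boundary loops after attachment removal, found %d",
          length(loops))
  }
  loop_cent <- lapply(loops, function(l) {
    colMeans(open_mesh$vertices[as.integer(l), , drop = FALSE])
  })
  d_o <- vapply(loop_cent, function(c) vnorm(c - origin$centroid), 0)
  origin_loop <- loops[[which.min(d_o)]]
  insertion_loop <- loops[[which.max(d_o)]]

  field <- stage("field solve",
                 solve_field(open_mesh, origin_loop, insertion_loop))
  contours <- stage("contour stack",
                    contour_stack(field, n_segments - 1L, n_samples))
  levels <- seq_len(n_segments - 1L) / n_segments
  sections <- stage("template slicing",
                    slice_template(template, levels, n_samples))

  interior <- array(0, dim = c(n_fibers, n_segments - 1L, 3L))
  # parallel templates have identical sections; compute the weights once
  wts <- section_weights(sections[[1L]])
  for (k in seq_len(n_segments - 1L)) {
    sec <- sections[[k]]
    sec$weights <- if (template$kind == "parallel") wts else NULL
    interior[, k, ] <- map_section(sec, contours[[k]])
  }

  pts <- array(0, dim = c(n_fibers, n_segments + 1L, 3L))
  pts[, 2:n_segments, ] <- interior
  fibers <- fiber_set(pts, muscle = muscle$name)
  attr(fibers, "pending_endpoints") <- TRUE
  attr(fibers, "template") <- template
  attr(fibers, "n_samples") <- n_samples
  attr(fibers, "first_contour") <- contours[[1L]]$points
  attr(fibers, "last_contour") <- contours[[length(contours)]]$points

  fibers <- stage("attachment connection",
                  connect_attachments(fibers, origin, insertion))
  stage("fibre smoothing", smooth_fibers(fibers, lam))
}

#' Connect fibre endpoints to the attachment areas
#'
#' The template's end-face sections (z = 0 and z = 1) are mapped onto the
#' attachment outlines with the same mean-value machinery used for interior
#' contours: the outline is resampled like a contour, aligned to the nearest
#' interior contour, and each fibre's endpoint is the weighted combination
#' of the outline samples.  Endpoints therefore lie on the surface spanned
#' by the attachment outline.
#'
#' @param fibers a `fiber_set` produced by the decomposition pipeline (with
#'   interior points populated).
#' @param origin,insertion [attachment_area()]s.
#' @return the `fiber_set` with first and last points filled in.
#' @export
connect_attachments <- function(fibers, origin, insertion) {
  template <- attr(fibers, "template")
  n_samples <- attr(fibers, "n_samples") %||% 64L
  if (is.null(template)) {
    stopf("connect_attachments: fiber set lacks template metadata")
  }
  np <- fibers$n_points
  for (side in c("origin", "insertion")) {
    area <- if (side == "origin") origin else insertion
    ref <- if (side == "origin") attr(fibers, "first_contour") else
      attr(fibers, "last_contour")
    outline <- check_outline(area)
    outline <- resample_closed(outline, n_samples)
    outline <- align_cyclic(outline, ref)
    seeds <- template_face_points(template, if (side == "origin") 0 else 1)
    sec <- structure(list(level = NA_real_, fiber_points_2d = seeds,
                          boundary_polygon = unit_square_polygon(n_samples)),
                     class = "template_section")
    ends <- map_section(sec, list(points = outline))
    idx <- if (side == "origin") 1L else np
    fibers$points[, idx, ] <- ends
  }
  attr(fibers, "pending_endpoints") <- NULL
  fibers
}

check_outline <- function(area) {
  lm <- area$landmarks
  # collinearity check via the second singular value of the centred outline
  sv <- svd(sweep(lm, 2L, colMeans(lm)))$d
  if (sv[2L] < 1e-10 * max(sv[1L], 1e-300)) {
    stopf("attachment '%s' outline is degenerate (collinear landmarks)",
          area$name)
  }
  lm
}

# Fibre seed positions on the z = 0 or z = 1 template face.
template_face_points <- function(template, z) {
  t(vapply(template$control_points, function(cp) {
    bezier_point(cp, z)[1:2]
  }, numeric(2L)))
}

#' Quadratic smoothing of fibre polylines
#'
#' Per fibre and coordinate, minimises
#' `sum ||p_k - q_k||^2 + lam * sum ||q_{k-1} - 2 q_k + q_{k+1}||^2`
#' with both endpoints held fixed, a small symmetric positive-definite
#' banded solve.  `lam = 0` returns the input unchanged; fibres whose second
#' differences already vanish (collinear equispaced points) are unchanged
#' for any `lam`.
#'
#' @param fibers a `fiber_set`.
#' @param lam smoothing penalty weight (>= 0, default 1).
#' @return the smoothed `fiber_set`.
#' @export
smooth_fibers <- function(fibers, lam = 1) {
  if (lam < 0) stopf("lam must be >= 0")
  if (lam == 0) return(fibers)
  np <- fibers$n_points
  if (np < 3L) return(fibers)

  # second-difference operator on all np points
  D <- matrix(0, np - 2L, np)
  for (k in seq_len(np - 2L)) D[k, k:(k + 2L)] <- c(1, -2, 1)
  H <- diag(np) + lam * crossprod(D)
  int <- 2:(np - 1L)
  Hii <- H[int, int, drop = FALSE]
  Hib <- H[int, c(1L, np), drop = FALSE]
  Hinv <- solve(Hii)

  out <- fibers
  for (i in seq_len(fibers$n_fibers)) {
    for (j in 1:3) {
      p <- fibers$points[i, , j]
      rhs <- p[int] - Hib %*% p[c(1L, np)]
      out$points[i, int, j] <- Hinv %*% rhs
    }
  }
  out
}

#' Export a fibre set to JSON
#'
#' Schema: `{muscle, n_fibers, n_segments, points, units: "m"}` with
#' `points` a fibre-major nested array.
#'
#' @param fibers a `fiber_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fiber_set <- function(fibers, path) {
  pts <- lapply(seq_len(fibers$n_fibers), function(i) {
    lapply(seq_len(fibers$n_points), function(k) {
      as.numeric(fibers$points[i, k, ])
    })
  })
  jsonlite::write_json(list(muscle = fibers$muscle,
                            n_fibers = fibers$n_fibers,
                            n_segments = fibers$n_points - 1L,
                            points = pts, units = "m"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fibre set from JSON
#'
#' @param path JSON file written by [write_fiber_set()].
#' @return a `fiber_set`.
#' @export
read_fiber_set <- function(path) {
  if (!file.exists(path)) stopf("fiber set file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pts <- doc$points   # n_fibers x n_points x 3 array after simplification
  if (is.list(pts)) pts <- simplify2array(pts)
  arr <- array(0, dim = c(doc$n_fibers, doc$n_segments + 1L, 3L))
  for (i in seq_len(doc$n_fibers)) arr[i, , ] <- pts[i, , ]
  fiber_set(arr, muscle = doc$muscle)
}

#' Export a fibre set to CSV
#'
#' Columns: `fiber_id, point_id, x, y, z` (metres).
#'
#' @param fibers a `fiber_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fiber_csv <- function(fibers, path) {
  n <- fibers$n_fibers
  np <- fibers$n_points
  df <- data.frame(
    fiber_id = rep(seq_len(n), each = np),
    point_id = rep(seq_len(np), times = n),
    x = as.vector(t(fibers$points[, , 1L])),
    y = as.vector(t(fibers$points[, , 2L])),
    z = as.vector(t(fibers$points[, , 3L])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
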