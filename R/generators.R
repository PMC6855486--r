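#' Specification of a random digraph class
#'
#' Three study classes are predefined. `"G1"`: Erdos-Renyi digraphs with 9
#' vertices and 8-36 edges. `"G21"`: 4-level hierarchical digraphs with all
#' edges pointing toward the root level and 5-30 vertices. `"G22"`:
#' hierarchical digraphs with exactly 20 vertices and 8-30 edges.
#'
#' @param class `"G1"`, `"G21"` or `"G22"`.
#' @param size number of graphs to draw with [sample_class()].
#' @param seed integer random seed.
#' @param n_range vertex-count range (fixed count = both ends equal).
#' @param m_range edge-count range; `NULL` for the hierarchical default
#'   (target drawn uniformly between the mandatory upward edges and
#'   `ceiling(1.5 |V|)`, capped by the number of admissible upward pairs).
#' @param levels number of hierarchy levels (root level is level 0).
#' @param step_prob probability that a mandatory upward edge targets the
#'   adjacent level rather than jumping at least two levels.
#' @return object of class `class_spec`.
#' @export
class_spec <- function(class = c("G1", "G21", "G22"), size = 100L,
                       seed = NULL, n_range = NULL, m_range = NULL,
                       levels = 4L, step_prob = 0.7) {
  class <- match.arg(class)
  defaults <- switch(class,
    G1  = list(n_range = c(9L, 9L), m_range = c(8L, 36L)),
    G21 = list(n_range = c(5L, 30L), m_range = NULL),
    G22 = list(n_range = c(20L, 20L), m_range = c(8L, 30L)))
  if (is.null(n_range)) n_range <- defaults$n_range
  if (is.null(m_range) && class != "G21") m_range <- defaults$m_range
  stopifnot(length(n_range) == 2, n_range[1] >= 1, n_range[1] <= n_range[2],
            size >= 0, step_prob >= 0, step_prob <= 1)
  if (class != "G1" && n_range[1] < levels) {
    stop("need at least ", levels, " vertices for ", levels,
         " non-empty levels")
  }
  structure(list(class = class, size = as.integer(size), seed = seed,
                 n_range = as.integer(n_range), m_range = m_range,
                 levels = as.integer(levels), step_prob = step_prob),
            class = "class_spec")
}

#' Random weakly connected Erdos-Renyi digraph
#'
#' Draws the edge count m uniformly from `m_range`, then m distinct ordered
#' pairs uniformly (the directed G(n, m) model); rejection-samples until the
#' result is weakly connected.
#'
#' @param n number of vertices.
#' @param m_range integer range for the edge count; needs
#'   `m_range[1] >= n - 1` (connectivity possible) and
#'   `m_range[2] <= n (n - 1)`.
#' @param max_tries rejection cap.
#' @return a weakly connected simple directed `igraph` object.
#' @export
erdos_renyi_digraph <- function(n, m_range = c(n - 1L, n * (n - 1L)),
                                max_tries = 1000L) {
  stopifnot(n >= 2, length(m_range) == 2, m_range[1] <= m_range[2])
  if (m_range[2] > n * (n - 1)) stop("m_range exceeds n(n-1) ordered pairs")
  if (m_range[1] < n - 1) stop("m_range[1] < n - 1: connectivity impossible")
  for (try in seq_len(max_tries)) {
    m <- if (m_range[1] == m_range[2]) m_range[1] else
      sample(seq.int(m_range[1], m_range[2]), 1L)
    g <- igraph::sample_gnm(n, m, directed = TRUE)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    if (igraph::is_connected(g, mode = "weak")) return(g)
  }
  stop("no weakly connected graph found in ", max_tries, " attempts")
}

#' Random hierarchical (layered) digraph
#'
#' Vertices are partitioned into non-empty levels 0..(levels-1); level 0 is
#' the root level and every edge points from a higher level toward level 0.
#' Each non-root vertex receives one mandatory upward edge (adjacent level
#' with probability `step_prob`, otherwise a jump of at least two levels
#' where possible); extra upward edges are then added uniformly among the
#' unused upward pairs until the target edge count. Weak connectivity is
#' enforced by rejection.
#'
#' @param spec a `class_spec` with class `"G21"` or `"G22"`.
#' @param max_tries rejection cap.
#' @return a weakly connected simple directed `igraph` object with vertex
#'   attribute `level`.
#' @export
hierarchical_digraph <- function(spec, max_tries = 1000L) {
  stopifnot(inherits(spec, "class_spec"))
  if (spec$class == "G1") stop("hierarchical generator needs class G21 or G22")
  L <- spec$levels
  for (try in seq_len(max_tries)) {
    n <- if (spec$n_range[1] == spec$n_range[2]) spec$n_range[1] else
      sample(seq.int(spec$n_range[1], spec$n_range[2]), 1L)
    sizes <- uniform_composition(n, L)
    level <- rep(seq_len(L) - 1L, times = sizes)
    # upward pairs: from vertex at level i to any vertex at level < i
    mand <- n - sizes[1L]
    max_up <- sum(vapply(seq_len(L - 1L) + 0L, function(i)
      sizes[i + 1L] * sum(sizes[seq_len(i)]), numeric(1)))
    if (is.null(spec$m_range)) {
      m_hi <- min(ceiling(1.5 * n), max_up)
      m <- if (mand >= m_hi) mand else sample(seq.int(mand, m_hi), 1L)
    } else {
      m <- sample(seq.int(spec$m_range[1], spec$m_range[2]), 1L)
      if (m < mand || m > max_up) next  # level split incompatible, resample
    }
    edges <- matrix(integer(0), ncol = 2)
    for (v in which(level > 0L)) {
      lv <- level[v]
      jump_ok <- lv >= 2L
      to_level <- if (!jump_ok || stats::runif(1) < spec$step_prob) {
        lv - 1L
      } else {
        lower <- seq_len(lv - 1L) - 1L  # levels 0 .. lv-2
        if (length(lower) == 1L) lower else sample(lower, 1L)
      }
      tgt <- which(level == to_level)
      edges <- rbind(edges, c(v, if (length(tgt) == 1L) tgt else
        sample(tgt, 1L)))
    }
    if (m > mand) {
      up <- which(outer(level, level, ">"), arr.ind = TRUE)  # from, to
      used <- paste(edges[, 1], edges[, 2])
      free <- up[!(paste(up[, 1], up[, 2]) %in% used), , drop = FALSE]
      extra <- free[sample.int(nrow(free), m - mand), , drop = FALSE]
      edges <- rbind(edges, extra)
    }
    g <- igraph::make_empty_graph(n, directed = TRUE)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    igraph::V(g)$level <- level
    g <- igraph::add_edges(g, t(edges))
    if (igraph::is_connected(g, mode = "weak")) return(g)
  }
  stop("no weakly connected hierarchical graph found in ", max_tries,
       " attempts")
}

# uniform composition of n into k positive parts (cut-point method)
uniform_composition <- function(n, k) {
  if (k == 1L) return(n)
  cuts <- sort(sample.int(n - 1L, k - 1L))
  diff(c(0L, cuts, n))
}

#' Draw one graph from a class specification
#'
#' @param spec a `class_spec`.
#' @param max_tries rejection cap.
#' @return a weakly connected simple directed `igraph` object.
#' @export
generate_digraph <- function(spec, max_tries = 1000L) {
  stopifnot(inherits(spec, "class_spec"))
  if (spec$class == "G1") {
    erdos_renyi_digraph(spec$n_range[1], spec$m_range, max_tries)
  } else {
    hierarchical_digraph(spec, max_tries)
  }
}

#' Exact digraph isomorphism
#'
#' Degree-class counts (both directions) act as a fast rejection prefilter;
#' exact decision by VF2.
#'
#' @param g,h simple digraphs.
#' @return logical scalar.
#' @export
are_isomorphic <- function(g, h) {
  validate_digraph(g); validate_digraph(h)
  if (igraph::vcount(g) != igraph::vcount(h) ||
      igraph::ecount(g) != igraph::ecount(h)) return(FALSE)
  if (degree_class_key(g) != degree_class_key(h)) return(FALSE)
  igraph::is_isomorphic_to(g, h, method = "vf2")
}

# invariant fingerprint used for iso-prefiltering and bucketing
degree_class_key <- function(g) {
  paste(paste(degree_class_counts(g, "out"), collapse = ","),
        paste(degree_class_counts(g, "in"), collapse = ","), sep = "|")
}

#' Sample a class of pairwise non-isomorphic connected digraphs
#'
#' Repeatedly draws graphs from the class generator, keeps only weakly
#' connected graphs not isomorphic to any already accepted graph
#' (degree-class-count buckets + VF2 within a bucket), and stops at the
#' requested size or when the attempt budget is exhausted (then returns the
#' partial sample with a warning).
#'
#' @param spec a `class_spec`; its `size` and `seed` fields drive the run.
#' @param attempts_per_graph attempt budget, multiplied by `size`.
#' @return list of digraphs of length at most `spec$size`.
#' @export
sample_class <- function(spec, attempts_per_graph = 200L) {
  stopifnot(inherits(spec, "class_spec"))
  runner <- function() {
    out <- vector("list", spec$size)
    buckets <- new.env(parent = emptyenv())
    got <- 0L
    budget <- spec$size * attempts_per_graph
    tries <- 0L
    while (got < spec$size && tries < budget) {
      tries <- tries + 1L
      g <- generate_digraph(spec)
      key <- degree_class_key(g)
      idx <- if (is.null(buckets[[key]])) integer(0) else buckets[[key]]
      dup <- FALSE
      for (i in idx) {
        if (igraph::is_isomorphic_to(out[[i]], g, method = "vf2")) {
          dup <- TRUE
          break
        }
      }
      if (!dup) {
        got <- got + 1L
        out[[got]] <- g
        buckets[[key]] <- c(idx, got)
      }
    }
    if (got < spec$size) {
      warning("only ", got, " of ", spec$size,
              " pairwise non-isomorphic graphs found within ", budget,
              " attempts")
    }
    out[seq_len(got)]
  }
  if (is.null(spec$seed)) runner() else withr::with_seed(spec$seed, runner())
}
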