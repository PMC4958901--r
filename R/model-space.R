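## The candidate model space: 20 network architectures over
## preSMA, IFG, STN and M1, varying (i) the average frontal-frontal coupling
## (family A = absent, B = IFG->preSMA, C = preSMA->IFG, D = bidirectional)
## and (ii) how successful stopping enters (12 bilinear models in which the
## stopping contrast modulates a cortico-subcortical connection; 8 non-linear
## models in which stopping drives a frontal region whose activity gates the
## other frontal region's projection to the STN).

#' Default region set of the response inhibition network
#'
#' Ordered labels for the four-node network: pre-supplementary motor area,
#' inferior frontal gyrus, subthalamic nucleus and primary motor cortex.
#'
#' @param names character vector of unique region labels (at least two)
#' @return object of class \code{region_set}
#' @export
region_set <- function(names = c("preSMA", "IFG", "STN", "M1")) {
  stopifnot(is.character(names), length(names) >= 2, !anyDuplicated(names))
  structure(list(names = names, n = length(names)), class = "region_set")
}

input_channels <- c("task", "stop")

empty_masks <- function(regions, n_inputs = 2L) {
  n <- regions$n
  nm <- regions$names
  A <- matrix(FALSE, n, n, dimnames = list(nm, nm))   # row = target, col = source
  B <- array(FALSE, c(n, n, n_inputs), dimnames = list(nm, nm, input_channels[seq_len(n_inputs)]))
  C <- matrix(FALSE, n, n_inputs, dimnames = list(nm, input_channels[seq_len(n_inputs)]))
  D <- array(FALSE, c(n, n, n), dimnames = list(nm, nm, nm))  # slice = gating source
  list(A = A, B = B, C = C, D = D)
}

#' Construct a single candidate network specification
#'
#' @param id short model label (e.g. \code{"NCp"})
#' @param family one of \code{"A"},\code{"B"},\code{"C"},\code{"D"}: the
#'   average frontal-frontal connectivity pattern (absent / IFG to preSMA /
#'   preSMA to IFG / bidirectional)
#' @param linearity \code{"linear"} (stopping modulates a connection,
#'   B matrix) or \code{"nonlinear"} (stopping drives a frontal region that
#'   gates the other frontal projection to STN, D matrix)
#' @param gating_source for non-linear models, \code{"preSMA"} or \code{"IFG"}
#' @param modulation_placement for linear models, which cortico-subcortical
#'   connection carries the stopping modulation: \code{"IFG->STN"},
#'   \code{"preSMA->STN"} or \code{"both"}
#' @param regions a \code{\link{region_set}}
#' @param backbone character vector of "src->tgt" average connections shared
#'   by every model (in addition to self-connections and the family-specific
#'   frontal-frontal coupling)
#' @return object of class \code{dcm_model}
#' @export
model_spec <- function(id, family = c("A", "B", "C", "D"),
                       linearity = c("linear", "nonlinear"),
                       gating_source = c("none", "preSMA", "IFG"),
                       modulation_placement = c("none", "IFG->STN", "preSMA->STN", "both"),
                       regions = region_set(),
                       backbone = c("preSMA->STN", "IFG->STN", "STN->M1")) {
  family <- match.arg(family)
  linearity <- match.arg(linearity)
  gating_source <- match.arg(gating_source)
  modulation_placement <- match.arg(modulation_placement)
  if (linearity == "nonlinear" && gating_source == "none")
    stop("non-linear models need a gating source")
  if (linearity == "linear" && modulation_placement == "none")
    stop("linear models need a modulation placement")
  if (linearity == "linear") gating_source <- "none"
  if (linearity == "nonlinear") modulation_placement <- "none"

  masks <- empty_masks(regions)
  nm <- regions$names
  set_edge <- function(M, edge) {
    parts <- strsplit(edge, "->", fixed = TRUE)[[1]]
    M[parts[2], parts[1]] <- TRUE
    M
  }
  diag(masks$A) <- TRUE
  for (e in backbone) masks$A <- set_edge(masks$A, e)
  frontal <- switch(family,
    A = character(0),
    B = "IFG->preSMA",
    C = "preSMA->IFG",
    D = c("IFG->preSMA", "preSMA->IFG"))
  for (e in frontal) masks$A <- set_edge(masks$A, e)

  # driving input "all trials" to both frontal regions, never to STN or M1
  masks$C[c("preSMA", "IFG"), "task"] <- TRUE

  if (linearity == "linear") {
    edges <- switch(modulation_placement,
      `IFG->STN` = "IFG->STN", `preSMA->STN` = "preSMA->STN",
      both = c("IFG->STN", "preSMA->STN"))
    for (e in edges) masks$B[, , "stop"] <- set_edge(masks$B[, , "stop"], e)
  } else {
    gated <- if (gating_source == "preSMA") "IFG->STN" else "preSMA->STN"
    masks$D[, , gating_source] <- set_edge(masks$D[, , gating_source], gated)
    # the stopping contrast drives the gating region (non-linear models only)
    masks$C[gating_source, "stop"] <- TRUE
  }

  spec <- structure(list(id = id, family = family, linearity = linearity,
                         gating_source = gating_source,
                         modulation_placement = modulation_placement,
                         regions = regions, masks = masks),
                    class = "dcm_model")
  validate_model_spec(spec)
  spec
}

validate_model_spec <- function(spec) {
  m <- spec$masks
  if (!all(diag(m$A))) stop("self-connections must be present")
  has_b <- any(m$B)
  has_d <- any(m$D)
  if (has_b == has_d)
    stop("exactly one of the B mask (linear) or D mask (non-linear) must be non-empty")
  drive <- rownames(m$C)[m$C[, "task"]]
  if (!setequal(intersect(drive, c("STN", "M1")), character(0)))
    stop("STN and M1 must not receive driving input")
  invisible(spec)
}

#' Enumerate the 20-model space of the response inhibition network
#'
#' Twelve linear models (4 families x 3 stopping-modulation placements) and
#' eight non-linear models (4 families x 2 gating sources), each family
#' holding five models.
#'
#' @param regions a \code{\link{region_set}}
#' @param backbone shared average connections, see \code{\link{model_spec}}
#' @return object of class \code{dcm_model_space}: a list of
#'   \code{dcm_model} specs with a \code{counts} attribute
#' @export
enumerate_models <- function(regions = region_set(),
                             backbone = c("preSMA->STN", "IFG->STN", "STN->M1")) {
  fams <- c("A", "B", "C", "D")
  placements <- c("IFG->STN", "preSMA->STN", "both")
  pl_code <- c(`IFG->STN` = "i", `preSMA->STN` = "p", both = "b")
  models <- list()
  for (f in fams) {
    for (p in placements) {
      id <- paste0("L", f, pl_code[[p]])
      models[[id]] <- model_spec(id, family = f, linearity = "linear",
                                 modulation_placement = p, regions = regions,
                                 backbone = backbone)
    }
  }
  for (f in fams) {
    for (g in c("preSMA", "IFG")) {
      id <- paste0("N", f, if (g == "preSMA") "p" else "i")
      models[[id]] <- model_spec(id, family = f, linearity = "nonlinear",
                                 gating_source = g, regions = regions,
                                 backbone = backbone)
    }
  }
  counts <- list(total = length(models),
                 linear = sum(vapply(models, function(m) m$linearity == "linear", TRUE)),
                 nonlinear = sum(vapply(models, function(m) m$linearity == "nonlinear", TRUE)),
                 per_family = table(vapply(models, function(m) m$family, "")))
  structure(models, counts = counts, class = "dcm_model_space")
}

#' @export
print.dcm_model_space <- function(x, ...) {
  ct <- attr(x, "counts")
  cat("Model space:", ct$total, "models (", ct$linear, "linear,",
      ct$nonlinear, "non-linear )\n")
  cat("Families:", paste(names(ct$per_family), as.integer(ct$per_family),
                         sep = "=", collapse = "  "), "\n")
  cat("Ids:", paste(vapply(x, `[[`, "", "id"), collapse = " "), "\n")
  invisible(x)
}

edge_labels <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(character(0))
  paste0(colnames(mask)[idx[, 2]], "->", rownames(mask)[idx[, 1]])
}

#' List the free parameters of a model specification
#'
#' @param spec a \code{dcm_model} or a model id looked up in \code{space}
#' @param space optional \code{dcm_model_space} for id lookup
#' @return list with per-matrix connection labels and the free parameter
#'   count (coupling plus per-region haemodynamic parameters)
#' @export
describe_model <- function(spec, space = NULL) {
  if (is.character(spec)) {
    space <- space %||% enumerate_models()
    if (is.null(space[[spec]])) stop("unknown model id: ", spec)
    spec <- space[[spec]]
  }
  m <- spec$masks
  nm <- spec$regions$names
  A_edges <- edge_labels(m$A & !diag(TRUE, spec$regions$n))
  self <- paste0("self:", nm)
  B_edges <- unlist(lapply(dimnames(m$B)[[3]], function(ch) {
    e <- edge_labels(m$B[, , ch])
    if (length(e)) paste0(ch, ":", e) else character(0)
  }))
  C_edges <- unlist(lapply(colnames(m$C), function(ch) {
    r <- rownames(m$C)[m$C[, ch]]
    if (length(r)) paste0(ch, "->", r) else character(0)
  }))
  D_edges <- unlist(lapply(nm, function(g) {
    e <- edge_labels(m$D[, , g])
    if (length(e)) paste0(e, " gated-by ", g) else character(0)
  }))
  n_hemo <- 3L * spec$regions$n
  n_coupling <- length(A_edges) + length(self) + length(B_edges) +
    length(C_edges) + length(D_edges)
  list(id = spec$id, family = spec$family, linearity = spec$linearity,
       A = A_edges, self = self, B = B_edges, C = C_edges, D = D_edges,
       n_coupling = n_coupling, n_hemodynamic = n_hemo,
       n_free = n_coupling + n_hemo)
}

#' Export a model-space manifest as JSON
#'
#' Masks are written as 0/1 tables (rows = target region, columns = source
#' region or input channel).
#'
#' @param space a \code{dcm_model_space}
#' @param path output file
#' @export
export_model_space <- function(space, path) {
  out <- lapply(unclass(space), function(sp) {
    m <- sp$masks
    list(id = sp$id, family = sp$family, linearity = sp$linearity,
         gating_source = sp$gating_source,
         modulation_placement = sp$modulation_placement,
         A = unname(apply(m$A, 1, as.integer, simplify = FALSE)),
         B_stop = unname(apply(m$B[, , "stop"], 1, as.integer, simplify = FALSE)),
         C = unname(apply(m$C, 1, as.integer, simplify = FALSE)),
         D = setNames(lapply(sp$regions$names, function(g)
           unname(apply(m$D[, , g], 1, as.integer, simplify = FALSE))),
           sp$regions$names))
  })
  jsonlite::write_json(list(regions = space[[1]]$regions$names, models = out),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
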