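#' Ontology objects
#'
#' A minimal directed-acyclic ontology: a table of terms and child->parent
#' edges restricted to `is_a` and `part_of` relationships, which are treated
#' identically for ancestor propagation (both denote containment for the
#' purpose of annotation closure).
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param parents named list mapping each term id to a character vector of
#'   parent term ids (possibly empty).
#' @return an `ontology` object.
#' @export
ontology <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$id)) stop_np("duplicate term ids")
  known <- terms$id
  parents <- parents[known[known %in% names(parents)]]
  missing <- setdiff(names(parents), known)
  if (length(missing)) stop_np("parent map references unknown terms: ",
                               paste(missing, collapse = ", "))
  for (id in names(parents)) {
    dangling <- setdiff(parents[[id]], known)
    if (length(dangling))
      stop_np(sprintf("edge from '%s' to unknown term(s): %s", id,
                      paste(dangling, collapse = ", ")))
  }
  full <- stats::setNames(vector("list", length(known)), known)
  full[names(parents)] <- parents
  full <- lapply(full, function(p) unique(as.character(p %||% character(0))))
  obj <- structure(list(terms = terms, parents = full), class = "ontology")
  cyc <- find_cycle(obj)
  if (!is.null(cyc))
    stop_np("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  obj
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology with %d terms, %d edges\n",
              nrow(x$terms), sum(lengths(x$parents))))
  invisible(x)
}

# Returns one cycle (as a term path) or NULL if the edge graph is acyclic.
find_cycle <- function(ont) {
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  path <- character(0)
  found <- NULL
  visit <- function(id) {
    if (!is.null(found)) return()
    s <- state[[id]] %||% 0L
    if (s == 2L) return()
    if (s == 1L) {
      i <- match(id, path)
      found <<- c(path[i:length(path)], id)
      return()
    }
    state[[id]] <- 1L
    path <<- c(path, id)
    for (p in ont$parents[[id]]) visit(p)
    path <<- path[-length(path)]
    state[[id]] <- 2L
  }
  for (id in names(ont$parents)) {
    visit(id)
    if (!is.null(found)) return(found)
  }
  NULL
}

#' Ancestors of an ontology term
#'
#' All terms reachable from `term` by following `is_a`/`part_of` edges
#' towards the root(s); `term` itself is not included.
#'
#' @param ont an [ontology()].
#' @param term a term id.
#' @return character vector of ancestor term ids.
#' @export
ontology_ancestors <- function(ont, term) {
  stopifnot(inherits(ont, "ontology"))
  if (!term %in% ont$terms$id) stop_np("unknown term: ", term)
  out <- character(0)
  frontier <- ont$parents[[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(ont$parents[new], use.names = FALSE))
  }
  sort(out)
}

#' Read an OBO-format ontology subset
#'
#' Parses `[Term]` stanzas of an OBO 1.2 file.  Only `is_a` and
#' `relationship: part_of` edges are retained; every other relationship
#' type is ignored.  Obsolete terms are dropped together with their edges.
#' Acyclicity and edge-endpoint validity are verified on load.
#'
#' @param path path to an OBO file.
#' @return an [ontology()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop_np("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return()
    ids <<- c(ids, cur$id)
    nms <<- c(nms, cur$name %||% cur$id)
    nss <<- c(nss, cur$namespace %||% "unknown")
    parents[[cur$id]] <<- unique(cur$parents)
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); cur <- list(parents = character(0)); in_term <- TRUE; next
    }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
    else if (grepl("^is_a:", ln))
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    else if (grepl("^relationship:\\s*part_of\\s", paste0(ln, " ")))
      cur$parents <- c(cur$parents,
                       trimws(sub("^relationship:\\s*part_of\\s+", "", ln)))
  }
  flush()
  terms <- data.frame(id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE)
  # edges pointing at obsolete/unknown terms are an input error, except that
  # edges *from* dropped terms vanished with the term itself
  ontology(terms, parents)
}
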