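#' Construct a food ontology
#'
#' A rooted category tree (e.g. plant -> fruit -> blueberry) plus
#' assignments of reference samples to leaf categories. Levels are computed
#' as depth from the root (root = 0) and validated.
#'
#' @param nodes data.frame with columns `category_id`, `name`, `parent_id`
#'   (`NA` for the root).
#' @param assignments named character vector mapping sample_id to a leaf
#'   category_id.
#' @return Object of class `food_ontology` with elements `nodes` (including
#'   a computed `level` column) and `assignments`.
#' @export
food_ontology <- function(nodes, assignments = character()) {
  if (!is.data.frame(nodes) || !all(c("category_id", "name", "parent_id") %in% names(nodes)))
    stop("nodes must have columns category_id, name, parent_id")
  nodes$category_id <- as.character(nodes$category_id)
  nodes$name <- as.character(nodes$name)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$parent_id[nodes$parent_id %in% c("", "NA")] <- NA_character_
  if (anyDuplicated(nodes$category_id)) stop("duplicate category_id")
  root <- which(is.na(nodes$parent_id))
  if (length(root) != 1L)
    stop("ontology must have exactly one root, found ", length(root))
  unknown_parent <- setdiff(stats::na.omit(nodes$parent_id), nodes$category_id)
  if (length(unknown_parent))
    stop("unknown parent id(s): ", paste(unknown_parent, collapse = ", "))
  # levels by iterative relaxation; failure to converge means a cycle
  level <- rep(NA_integer_, nrow(nodes))
  level[root] <- 0L
  for (iter in seq_len(nrow(nodes))) {
    pidx <- match(nodes$parent_id, nodes$category_id)
    newlev <- ifelse(is.na(nodes$parent_id), 0L, level[pidx] + 1L)
    if (identical(newlev, level)) break
    level <- newlev
  }
  if (anyNA(level)) {
    bad <- nodes$category_id[is.na(level)]
    stop("ontology contains a cycle involving: ", paste(bad, collapse = ", "))
  }
  nodes$level <- as.integer(level)
  assignments <- stats::setNames(as.character(assignments), names(assignments))
  if (length(assignments)) {
    if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
      stop("assignments must be a named vector (sample_id -> leaf category)")
    leaves <- setdiff(nodes$category_id, nodes$parent_id)
    unknown <- setdiff(assignments, nodes$category_id)
    if (length(unknown))
      stop("samples assigned to unknown categories: ", paste(unique(unknown), collapse = ", "))
    internal <- setdiff(unique(assignments), leaves)
    if (length(internal))
      stop("samples assigned to internal (non-leaf) categories: ",
           paste(internal, collapse = ", "))
  }
  structure(list(nodes = nodes, assignments = assignments),
            class = "food_ontology")
}

#' @export
print.food_ontology <- function(x, ...) {
  cat(sprintf("<food_ontology> %d categories, depth %d, %d assigned samples\n",
              nrow(x$nodes), max(x$nodes$level), length(x$assignments)))
  invisible(x)
}

ontology_leaves <- function(ontology) {
  setdiff(ontology$nodes$category_id, ontology$nodes$parent_id)
}

# all leaf categories in (or equal to) the subtree of `category`
subtree_leaves <- function(ontology, category) {
  nodes <- ontology$nodes
  members <- category
  repeat {
    kids <- nodes$category_id[!is.na(nodes$parent_id) & nodes$parent_id %in% members]
    add <- setdiff(kids, members)
    if (!length(add)) break
    members <- c(members, add)
  }
  intersect(members, ontology_leaves(ontology))
}

# samples (restricted to `samples`) assigned under category's subtree
subtree_samples <- function(ontology, category, samples) {
  leaves <- subtree_leaves(ontology, category)
  sids <- names(ontology$assignments)[ontology$assignments %in% leaves]
  intersect(samples, sids)
}

#' Read a food ontology from disk
#'
#' Two formats: a JSON document with a nested tree
#' `{"tree": {"id","name","children":[...]}, "assignments": {sample: leaf}}`,
#' or a TSV edge list with columns `child_id`, `parent_id`, `name` (root row
#' has an empty parent) plus a separate assignments TSV with columns
#' `sample_id`, `category_id`.
#'
#' @param path ontology file (`.json` or a delimited edge list).
#' @param assignments_path assignments TSV; only used for the edge-list
#'   format.
#' @return A [food_ontology].
#' @export
read_ontology <- function(path, assignments_path = NULL) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path)
    if (is.null(doc$tree)) stop("ontology JSON must contain a 'tree' object")
    rows <- list()
    walk <- function(node, parent) {
      if (is.null(node$id)) stop("ontology JSON node without 'id'")
      rows[[length(rows) + 1L]] <<- data.frame(
        category_id = as.character(node$id),
        name = as.character(node$name %||% node$id),
        parent_id = parent, stringsAsFactors = FALSE)
      for (ch in node$children %||% list()) walk(ch, as.character(node$id))
    }
    walk(doc$tree, NA_character_)
    assignments <- unlist(doc$assignments %||% list())
    food_ontology(do.call(rbind, rows), assignments)
  } else {
    df <- read_delim_auto(path)
    req <- c("child_id", "parent_id", "name")
    if (!all(req %in% names(df)))
      stop("edge list requires columns: ", paste(req, collapse = ", "))
    nodes <- data.frame(category_id = as.character(df$child_id),
                        name = as.character(df$name),
                        parent_id = as.character(df$parent_id),
                        stringsAsFactors = FALSE)
    assignments <- character()
    if (!is.null(assignments_path)) {
      adf <- read_delim_auto(assignments_path)
      if (!all(c("sample_id", "category_id") %in% names(adf)))
        stop("assignments TSV requires columns sample_id, category_id")
      assignments <- stats::setNames(as.character(adf$category_id),
                                     as.character(adf$sample_id))
    }
    food_ontology(nodes, assignments)
  }
}

#' Write a food ontology
#'
#' @param ontology a [food_ontology].
#' @param path output path; JSON (nested tree + assignments) when it ends
#'   in `.json`, otherwise a TSV edge list.
#' @param assignments_path where to write the assignments TSV in edge-list
#'   mode (default: `path` with an `_assignments.tsv` suffix).
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path, assignments_path = NULL) {
  stopifnot(inherits(ontology, "food_ontology"))
  nodes <- ontology$nodes
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    build <- function(id) {
      i <- match(id, nodes$category_id)
      kids <- nodes$category_id[!is.na(nodes$parent_id) & nodes$parent_id == id]
      node <- list(id = id, name = nodes$name[i])
      if (length(kids)) node$children <- lapply(kids, build)
      node
    }
    root <- nodes$category_id[is.na(nodes$parent_id)]
    doc <- list(tree = build(root),
                assignments = as.list(ontology$assignments))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    out <- data.frame(child_id = nodes$category_id,
                      parent_id = ifelse(is.na(nodes$parent_id), "", nodes$parent_id),
                      name = nodes$name, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    if (is.null(assignments_path))
      assignments_path <- sub("(\\.[^.]+)?$", "_assignments.tsv", path)
    adf <- data.frame(sample_id = names(ontology$assignments),
                      category_id = unname(ontology$assignments),
                      stringsAsFactors = FALSE)
    utils::write.table(adf, assignments_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Enumerate one-vs-rest discriminant contrasts
#'
#' One contrast per non-root category with enough samples: positives are the
#' provided samples assigned under the category's subtree; negatives are all
#' other provided samples (`scope = "global"`) or the other samples under
#' the same parent (`scope = "siblings"`). Contrasts whose positive or
#' negative group is smaller than `min_group_size` are dropped (the count is
#' attached as attribute `"dropped"`).
#'
#' @param ontology a [food_ontology].
#' @param samples character vector of sample ids to use (must be assigned).
#' @param scope `"global"` (category vs all other foods, the default) or
#'   `"siblings"`.
#' @param min_group_size minimum samples per class, >= 2.
#' @return list of contrast specs (`target_category`, `level`, `positives`,
#'   `negatives`, `scope`).
#' @export
enumerate_contrasts <- function(ontology, samples,
                                scope = c("global", "siblings"),
                                min_group_size = 3L) {
  scope <- match.arg(scope)
  stopifnot(inherits(ontology, "food_ontology"))
  if (min_group_size < 2L) stop("min_group_size must be >= 2")
  samples <- as.character(samples)
  unassigned <- setdiff(samples, names(ontology$assignments))
  if (length(unassigned))
    stop("samples without ontology assignment: ", paste(unassigned, collapse = ", "))
  nodes <- ontology$nodes
  nonroot <- nodes[!is.na(nodes$parent_id), , drop = FALSE]
  nonroot <- nonroot[order(nonroot$level, nonroot$category_id), , drop = FALSE]
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(nonroot))) {
    cat_id <- nonroot$category_id[i]
    pos <- subtree_samples(ontology, cat_id, samples)
    neg <- if (scope == "global") {
      setdiff(samples, pos)
    } else {
      setdiff(subtree_samples(ontology, nonroot$parent_id[i], samples), pos)
    }
    if (length(pos) < min_group_size || length(neg) < min_group_size) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <- list(target_category = cat_id,
                                    level = nonroot$level[i],
                                    positives = pos, negatives = neg,
                                    scope = scope)
  }
  if (!length(out))
    stop("no valid contrasts; consider a smaller min_group_size")
  attr(out, "dropped") <- dropped
  out
}
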