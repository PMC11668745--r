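#' Group summary FCN from per-subject networks
#'
#' The ratio matrix holds, for each ROI pair, the fraction of the group's
#' subjects whose FCN contains that edge; the summary adjacency keeps
#' edges whose ratio reaches the threshold (weak inequality, so ties at
#' the threshold survive). With `mode = "percentile"` the threshold is
#' instead the connectivity-ratio value at the given upper percentile of
#' the nonzero ratios.
#'
#' @param fcns non-empty list of [fcn()] objects sharing ROI labels.
#' @param threshold connectivity-ratio cutoff in (0, 1] (default 0.2), or
#'   the retained upper fraction when `mode = "percentile"`.
#' @param mode `"absolute"` (default) or `"percentile"`.
#' @param group group label carried on the result.
#' @return object of class `summary_fcn`: `ratio` matrix, binary
#'   `adjacency`, the `threshold` actually applied, `group`, `roi_labels`.
#' @export
group_summary <- function(fcns, threshold = 0.2,
                          mode = c("absolute", "percentile"),
                          group = NA_character_) {
  mode <- match.arg(mode)
  if (!length(fcns)) stop("empty group: no FCNs to summarize")
  stopifnot(all(vapply(fcns, inherits, logical(1), "fcn")),
            threshold > 0, threshold <= 1)
  labs <- fcns[[1]]$roi_labels
  ok <- vapply(fcns, function(f) identical(f$roi_labels, labs), logical(1))
  if (!all(ok)) stop("FCNs do not share one ROI label set")
  ratio <- Reduce(`+`, lapply(fcns, `[[`, "adjacency")) / length(fcns)
  diag(ratio) <- 0
  cut <- threshold
  if (mode == "percentile") {
    up <- ratio[upper.tri(ratio)]
    up <- up[up > 0]
    cut <- if (length(up)) stats::quantile(up, 1 - threshold, names = FALSE)
           else Inf
  }
  adjacency <- (ratio >= cut) * 1
  diag(adjacency) <- 0
  structure(list(ratio = ratio, adjacency = adjacency, threshold = cut,
                 mode = mode, group = group, roi_labels = labs,
                 n_subjects = length(fcns)),
            class = "summary_fcn")
}

#' @export
print.summary_fcn <- function(x, ...) {
  cat(sprintf(
    "<summary_fcn> group %s: %d subjects, threshold %.3g, %d edges\n",
    x$group, x$n_subjects, x$threshold, sum(x$adjacency) / 2))
  invisible(x)
}

#' Categorize ROIs across a two-group comparison
#'
#' Combines each group's top-quartile list with its near-origin flags
#' into one category per ROI: `both` (top-listed and near-origin in both
#' groups), `more_reactive_<g>` (top-listed in both, near-origin only in
#' group g), `only_<g>` (top-listed in exactly one group), else `none`.
#'
#' @param top_a,top_b [top_quartile_rois()] results for the two groups.
#' @param prox_a,prox_b [origin_proximity()] data frames for the two
#'   groups (their `near_origin` flags are used).
#' @param roi_names the common ROI universe; defaults to the ROI set
#'   behind `top_a`.
#' @return object of class `roi_category_map`: data.frame `categories`
#'   with columns `roi`, `category`, `in_top_a`, `in_top_b`,
#'   `near_origin_a`, `near_origin_b`, plus the two group labels.
#' @export
categorize_rois <- function(top_a, top_b, prox_a, prox_b, roi_names = NULL) {
  stopifnot(inherits(top_a, "top_roi_list"), inherits(top_b, "top_roi_list"))
  ga <- top_a$group; gb <- top_b$group
  if (is.null(roi_names)) roi_names <- sort(unique(c(
    prox_a$roi, prox_b$roi)))
  if (!setequal(prox_a$roi, roi_names) || !setequal(prox_b$roi, roi_names))
    stop("inconsistent ROI universes between the two groups")
  in_a <- roi_names %in% top_a$ranking$roi
  in_b <- roi_names %in% top_b$ranking$roi
  near_a <- prox_a$near_origin[match(roi_names, prox_a$roi)]
  near_b <- prox_b$near_origin[match(roi_names, prox_b$roi)]
  category <- ifelse(in_a & in_b & near_a & near_b, "both",
              ifelse(in_a & in_b & near_a & !near_b,
                     paste0("more_reactive_", ga),
              ifelse(in_a & in_b & !near_a & near_b,
                     paste0("more_reactive_", gb),
              ifelse(in_a & !in_b, paste0("only_", ga),
              ifelse(!in_a & in_b, paste0("only_", gb), "none")))))
  structure(list(categories = data.frame(
                   roi = roi_names, category = category,
                   in_top_a = in_a, in_top_b = in_b,
                   near_origin_a = near_a, near_origin_b = near_b,
                   row.names = NULL),
                 groups = c(ga, gb)),
            class = "roi_category_map")
}

#' @export
print.roi_category_map <- function(x, ...) {
  cat(sprintf("<roi_category_map> %s vs %s\n", x$groups[1], x$groups[2]))
  print(table(x$categories$category))
  invisible(x)
}

#' Direct-neighbor clusters of the categorized ROIs
#'
#' For every ROI carrying a category other than `none`, emits the ROI and
#' its direct neighbors in the summary adjacency as one named cluster
#' (letters A, B, C, ... in atlas order of the seed ROI). An isolated
#' categorized ROI yields a singleton cluster.
#'
#' @param summary a [group_summary()] result.
#' @param category_map a [categorize_rois()] result.
#' @return list of clusters, each a list with `name`, `roi` (seed),
#'   `category`, `members` (seed plus neighbors, seed first).
#' @export
extract_clusters <- function(summary, category_map) {
  stopifnot(inherits(summary, "summary_fcn"),
            inherits(category_map, "roi_category_map"))
  cat_df <- category_map$categories
  seeds <- cat_df$roi[cat_df$category != "none"]
  seeds <- seeds[order(match(seeds, summary$roi_labels))]
  out <- vector("list", length(seeds))
  letters_ext <- c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))
  for (i in seq_along(seeds)) {
    roi <- seeds[i]
    j <- match(roi, summary$roi_labels)
    if (is.na(j)) stop("categorized ROI not in the summary network: ", roi)
    nb <- summary$roi_labels[summary$adjacency[j, ] == 1]
    out[[i]] <- list(name = letters_ext[i], roi = roi,
                     category = cat_df$category[cat_df$roi == roi],
                     members = c(roi, nb))
  }
  out
}

#' Write the category map to CSV
#'
#' @param category_map a [categorize_rois()] result.
#' @param path CSV path.
#' @return invisibly the path.
#' @export
write_category_map <- function(category_map, path) {
  utils::write.csv(category_map$categories, path, row.names = FALSE)
  invisible(path)
}

#' Plot a colored group summary FCN
#'
#' Renders the summary network with the categorized ROIs highlighted:
#' `only_*` blue, `more_reactive_*` orange, `both` green, direct
#' neighbors of a categorized ROI in a lighter shade of its color,
#' everything else grey. Written as a vector-graphics PDF when `path` is
#' given, otherwise drawn on the current device.
#'
#' @param summary a [group_summary()] result.
#' @param category_map a [categorize_rois()] result.
#' @param path optional PDF output path.
#' @param seed layout seed.
#' @return invisibly the igraph object.
#' @export
plot_summary_fcn <- function(summary, category_map = NULL, path = NULL,
                             seed = 1L) {
  g <- igraph::graph_from_adjacency_matrix(summary$adjacency,
                                           mode = "undirected", diag = FALSE)
  col <- rep("grey80", length(summary$roi_labels))
  names(col) <- summary$roi_labels
  if (!is.null(category_map)) {
    cd <- category_map$categories
    shade <- function(cat) {
      if (cat == "both") c("#1b9e77", "#b3e2cd")
      else if (startsWith(cat, "more_reactive")) c("#d95f02", "#fdcdac")
      else c("#386cb0", "#b3cde3")
    }
    for (cl in extract_clusters(summary, category_map)) {
      cols <- shade(cl$category)
      nb <- setdiff(cl$members, cl$roi)
      col[nb[col[nb] == "grey80"]] <- cols[2]
      col[cl$roi] <- cols[1]
    }
  }
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  if (!is.null(path)) grDevices::pdf(path, width = 9, height = 9)
  plot(g, layout = lay, vertex.size = 4, vertex.color = col,
       vertex.label.cex = 0.4, vertex.label.color = "black",
       main = sprintf("Summary FCN: %s", summary$group))
  if (!is.null(path)) grDevices::dev.off()
  invisible(g)
}
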