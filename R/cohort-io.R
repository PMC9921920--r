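cohort_schema <- function() {
  c("participant_id", "sex",
    paste0("pa_", ipaq_items()$item),
    paste0("qeb_", qeb_items()),
    "height_cm", "weight_kg", "bfp_percent",
    "measured_flag", "measured_weight_kg", "measured_bfp_percent")
}

#' Write a cohort table to CSV
#'
#' One row per participant; missing cells are written empty.
#'
#' @param cohort Cohort data.frame.
#' @param path Output file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- intersect(c(cohort_schema(), "latent_class"), names(cohort))
  utils::write.csv(cohort[, cols], path, row.names = FALSE, na = "")
}

#' Read and validate a cohort table from CSV
#'
#' Checks the documented schema (errors list the offending columns),
#' validates every diet response against the six-level vocabulary
#' (errors report the participant id), and types the columns.
#'
#' @param path CSV path written by \code{write_cohort_csv()} or matching
#'   its schema.
#' @return Typed cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (nrow(raw) == 0) stop("empty cohort file: ", path)
  need <- cohort_schema()
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  vocab <- names(qeb_frequency_table())
  for (cn in paste0("qeb_", qeb_items())) {
    bad <- !is.na(raw[[cn]]) & !(raw[[cn]] %in% vocab)
    if (any(bad)) {
      stop("illegal diet category in column ", cn, " for participant(s) ",
           paste(raw$participant_id[bad], collapse = ", "), ": ",
           paste(unique(raw[[cn]][bad]), collapse = ", "))
    }
  }
  for (cn in paste0("pa_", ipaq_items()$item)) {
    raw[[cn]] <- as.numeric(raw[[cn]])
    if (anyNA(raw[[cn]]) || any(raw[[cn]] < 0)) {
      stop("column ", cn, " must contain nonnegative minutes")
    }
  }
  if (any(raw$height_cm <= 0) || any(raw$weight_kg <= 0)) {
    stop("heights and weights must be strictly positive")
  }
  raw$measured_flag <- as.logical(raw$measured_flag)
  raw
}

#' Export a dendrogram as a Newick string or file
#'
#' Branch lengths are parent merge height minus child merge height
#' (leaves sit at height 0), so leaf-to-ancestor path lengths equal the
#' ancestor's cophenetic height. Labels containing characters outside
#' [A-Za-z0-9_.|-] are single-quoted.
#'
#' @param tree An \code{hclust} object.
#' @param path Optional file path; when \code{NULL} the string is
#'   returned invisibly without writing.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  labs <- tree_labels(tree)
  merge <- tree$merge
  h <- tree$height
  quote_lab <- function(l) {
    if (grepl("[^A-Za-z0-9_.|-]", l)) paste0("'", gsub("'", "''", l), "'")
    else l
  }
  fmt <- function(x) sprintf("%.10g", x)
  node_str <- function(code, parent_h) {
    if (code < 0) {
      paste0(quote_lab(labs[-code]), ":", fmt(parent_h))
    } else {
      paste0("(", node_str(merge[code, 1], h[code]), ",",
             node_str(merge[code, 2], h[code]), "):",
             fmt(parent_h - h[code]))
    }
  }
  root <- nrow(merge)
  s <- paste0("(", node_str(merge[root, 1], h[root]), ",",
              node_str(merge[root, 2], h[root]), ");")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Write tanglegram layout coordinates as CSV
#'
#' @param tg A \code{tanglegram}.
#' @param path Output CSV path.
#' @export
write_tanglegram_csv <- function(tg, path) {
  lay <- tanglegram_layout(tg)
  utils::write.csv(lay$connectors, path, row.names = FALSE)
}

#' Render a tanglegram as a standalone SVG file
#'
#' Minimal deterministic rendering: the two facing dendrograms with
#' straight connectors between matching leaves, colored by subtree
#' group.
#'
#' @param tg A \code{tanglegram}.
#' @param path Output .svg path.
#' @param width,height Canvas size in pixels.
#' @export
write_tanglegram_svg <- function(tg, path, width = 800, height = 600) {
  lay <- tanglegram_layout(tg)
  n <- nrow(lay$left_leaves)
  pal <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e")
  ys <- function(y) 30 + (n - y) / max(n - 1, 1) * (height - 60)
  seg <- function(x1, y1, x2, y2, col) sprintf(
    '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s"/>',
    x1, y1, x2, y2, col)
  txt <- function(x, y, s, anchor) sprintf(
    '<text x="%.1f" y="%.1f" font-size="11" text-anchor="%s">%s</text>',
    x, y + 4, anchor, s)
  tree_segments <- function(tree, flips, side) {
    ord <- leaf_order_indices(tree, flips)
    posx <- if (side == "left") function(d) 150 + d
            else function(d) width - 150 - d
    hmax <- max(tree$height)
    depth <- function(hh) (hh / hmax) * 120
    ypos <- numeric(nrow(tree$merge))
    out <- character(0)
    leaf_y <- ys(n - match(seq_len(n), ord) + 1)
    node_y <- function(code) if (code < 0) leaf_y[-code] else ypos[code]
    node_x <- function(code) if (code < 0) posx(0) else posx(depth(tree$height[code]))
    for (s2 in seq_len(nrow(tree$merge))) {
      ya <- node_y(tree$merge[s2, 1]); yb <- node_y(tree$merge[s2, 2])
      xa <- node_x(tree$merge[s2, 1]); xb <- node_x(tree$merge[s2, 2])
      x <- posx(depth(tree$height[s2]))
      ypos[s2] <- (ya + yb) / 2
      out <- c(out, seg(x, ya, x, yb, "#555555"),
               seg(x, ya, xa, ya, "#555555"), seg(x, yb, xb, yb, "#555555"))
    }
    out
  }
  body <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    '<rect width="100%" height="100%" fill="white"/>',
    tree_segments(tg$left, tg$left_flips, "left"),
    tree_segments(tg$right, tg$right_flips, "right"),
    vapply(seq_len(n), function(i) {
      co <- lay$connectors[i, ]
      col <- pal[(co$group - 1) %% length(pal) + 1]
      seg(210, ys(co$y_left), width - 210, ys(co$y_right), col)
    }, character(1)),
    vapply(seq_len(n), function(i)
      txt(205, ys(lay$left_leaves$y[i]), lay$left_leaves$label[i], "end"),
      character(1)),
    vapply(seq_len(n), function(i)
      txt(width - 205, ys(lay$right_leaves$y[i]), lay$right_leaves$label[i],
          "start"), character(1)),
    "</svg>"
  )
  writeLines(body, path)
  invisible(path)
}
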