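# Fate -> display colour. Founders dark purple, the three recruitment waves
# progressively paler pink, border cells green, precursors unfilled.
fate_colors <- function() {
  c(PRECURSOR = NA, R8 = "#4B0082", PR_WAVE1 = "#C2185B",
    PR_WAVE2 = "#EC6FA8", PR_WAVE3 = "#F8BBD0", BORDER = "#2E8B57")
}

#' Render a simulation snapshot
#'
#' Draws one filled circle per cell (see `fate_colors` in the source for the
#' fate palette: R8 dark purple, waves progressively paler pink, border
#' green, precursors outline-only) plus the domain rectangle, and a dashed
#' vertical furrow line while the sweep is unfinished. SVG output is written
#' directly as text (deterministic, no graphics device needed); PNG uses the
#' standard \pkg{grDevices} device.
#'
#' @param state An `eye_sim` object or a bare `epithelium`.
#' @param path Output file path.
#' @param format `"svg"` or `"png"`.
#' @param width Output width in pixels (height follows the domain aspect).
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(state, path, format = c("svg", "png"),
                            width = 800) {
  format <- match.arg(format)
  if (inherits(state, "eye_sim")) {
    ep <- state$epithelium
    furrow_x <- if (state$furrow$finished) NULL else state$furrow$x
  } else {
    stopifnot(inherits(state, "epithelium"))
    ep <- state
    furrow_x <- NULL
  }
  dom <- view_box(ep)
  w <- dom[2] - dom[1]; h <- dom[4] - dom[3]
  if (w <= 0) w <- 1
  if (h <= 0) h <- 1
  height <- max(1, round(width * h / w))
  cols <- fate_colors()
  if (format == "svg") {
    sc <- width / w
    tx <- function(x) (x - dom[1]) * sc
    ty <- function(y) (dom[4] - y) * sc  # world y up -> svg y down
    lines <- c(
      sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
              width, height, width, height),
      sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white" stroke="black"/>',
              width, height))
    if (n_cells(ep) > 0) {
      fate_chr <- FATE_LEVELS[ep$fate]
      fill <- cols[fate_chr]
      fill[is.na(fill)] <- "none"
      lines <- c(lines, sprintf(
        '<circle cx="%.2f" cy="%.2f" r="%.2f" fill="%s" stroke="#888888" stroke-width="0.5" class="%s"/>',
        tx(ep$x), ty(ep$y), ep$r * sc, fill, fate_chr))
    }
    if (!is.null(furrow_x) && furrow_x >= dom[1] && furrow_x <= dom[2])
      lines <- c(lines, sprintf(
        '<line x1="%.2f" y1="0" x2="%.2f" y2="%d" stroke="black" stroke-dasharray="6,4" class="furrow"/>',
        tx(furrow_x), tx(furrow_x), height))
    lines <- c(lines, "</svg>")
    writeLines(lines, path)
  } else {
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit(graphics::par(op), add = TRUE)
    draw_cells(ep, furrow_x)
  }
  invisible(path)
}

# view rectangle: the reference domain, widened if the developed tissue has
# expanded past it
view_box <- function(ep) {
  dom <- ep$domain
  if (n_cells(ep) > 0) {
    dom <- c(min(dom[1], min(ep$x - ep$r)), max(dom[2], max(ep$x + ep$r)),
             min(dom[3], min(ep$y - ep$r)), max(dom[4], max(ep$y + ep$r)))
  }
  dom
}

# shared base-graphics drawing used by the png path and plot methods
draw_cells <- function(ep, furrow_x = NULL, main = NULL) {
  dom <- view_box(ep)
  cols <- fate_colors()
  plot(NA, xlim = dom[1:2], ylim = dom[3:4], asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = main)
  graphics::rect(dom[1], dom[3], dom[2], dom[4])
  if (n_cells(ep) > 0) {
    fill <- cols[FATE_LEVELS[ep$fate]]
    graphics::symbols(ep$x, ep$y, circles = ep$r, inches = FALSE,
                      add = TRUE, bg = fill, fg = "grey50")
  }
  if (!is.null(furrow_x))
    graphics::abline(v = furrow_x, lty = 2)
  invisible(NULL)
}

#' Plot a simulated eye layout
#'
#' @param x An `eye_sim` object.
#' @param ... Ignored.
#' @export
plot.eye_sim <- function(x, ...) {
  furrow_x <- if (x$furrow$finished) NULL else x$furrow$x
  draw_cells(x$epithelium, furrow_x,
             main = sprintf("%d eye units, cycle %d", length(x$units),
                            x$furrow$cycle))
}

#' @export
plot.epithelium <- function(x, ...) {
  draw_cells(x, NULL, main = sprintf("%d cells", n_cells(x)))
}
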