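#' Render the four cost-curve panels
#'
#' Reproduces the standard picture of the model as four panels:
#'
#' * **A** — startle cost, expected blow cost and their total over `r`, with
#'   the minimiser marked;
#' * **B** — the total cost at a raised blow probability: the expected blow
#'   cost is scaled up and the minimiser moves right;
#' * **C** — the direct and opportunity components shown separately at the
#'   baseline opportunity scale;
#' * **D** — the opportunity components scaled by a larger `eta`: the
#'   minimiser again moves right (given the opportunity-slope assumption).
#'
#' The family must pass [audit_assumptions()]; otherwise the function
#' refuses and prints the report. Minimisers are computed with
#' [optimal_startle()] and returned so that the marker ordering can be
#' checked programmatically without reading image files.
#'
#' @param family A [cost_family][make_cost_family] passing the audit.
#' @param p_pair Blow probabilities for panels A (first) and B (second).
#' @param eta_pair Opportunity scales for panels C (first) and D (second).
#' @param p_for_eta Blow probability held fixed in panels C and D.
#' @param out_dir Directory for image files; `NULL` computes the panels
#'   without writing.
#' @param format `"png"` or `"svg"`.
#' @param n_grid Curve resolution.
#' @return (Invisibly) a list with the four minimisers `r0_A`, `r0_B`,
#'   `r0_C`, `r0_D`, the ggplot objects `plots`, and the written `files`.
#' @export
render_cost_panels <- function(family = make_cost_family(),
                               p_pair = c(0.2, 0.6), eta_pair = c(1, 2),
                               p_for_eta = 0.3, out_dir = NULL,
                               format = c("png", "svg"), n_grid = 512L) {
  format <- match.arg(format)
  stopifnot(inherits(family, "cost_family"))
  if (length(p_pair) != 2L || p_pair[1] >= p_pair[2])
    stop("`p_pair` must be two increasing probabilities")
  if (length(eta_pair) != 2L || eta_pair[1] >= eta_pair[2])
    stop("`eta_pair` must be two increasing scales")
  audit <- audit_assumptions(family)
  if (!all(audit$passed)) {
    print(audit)
    stop("cost family fails the assumption audit; refusing to render")
  }

  r <- seq(0, family$r_max, length.out = n_grid)
  fam_eta <- function(eta) scale_opportunity(family, eta)
  startle_curve <- function(eta) startle_side_cost(fam_eta(eta), r)
  blow_curve <- function(p, eta) {
    f <- fam_eta(eta)
    p * (f$fns$c_b_direct(r) + eta * f$fns$c_b_forgone(r))
  }
  r0 <- function(p, eta)
    optimal_startle(fam_eta(eta), p, check_assumptions = FALSE)$r0

  r0_A <- r0(p_pair[1], eta_pair[1])
  r0_B <- r0(p_pair[2], eta_pair[1])
  r0_C <- r0(p_for_eta, eta_pair[1])
  r0_D <- r0(p_for_eta, eta_pair[2])

  curve_df <- function(p, eta) {
    data.frame(r = rep(r, 3),
               cost = c(startle_curve(eta), blow_curve(p, eta),
                        total_cost(fam_eta(eta), p, r)),
               component = rep(c("startle cost", "expected blow cost",
                                 "total"), each = length(r)))
  }
  base_theme <- ggplot2::theme_minimal(base_size = 10)
  panel <- function(df, markers, title) {
    ggplot2::ggplot(df, ggplot2::aes(x = r, y = cost,
                                     colour = component,
                                     linetype = component)) +
      ggplot2::geom_line(linewidth = 0.7) +
      ggplot2::geom_vline(xintercept = markers, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::labs(title = title, x = "startle magnitude r", y = "cost") +
      base_theme
  }

  p_A <- panel(curve_df(p_pair[1], eta_pair[1]), r0_A,
               sprintf("A: cost components, P(B|X) = %g", p_pair[1]))
  df_B <- rbind(
    cbind(curve_df(p_pair[1], eta_pair[1]),
          p = sprintf("P(B|X) = %g", p_pair[1])),
    cbind(curve_df(p_pair[2], eta_pair[1]),
          p = sprintf("P(B|X) = %g", p_pair[2])))
  df_B <- df_B[df_B$component == "total", ]
  p_B <- ggplot2::ggplot(df_B, ggplot2::aes(x = r, y = cost,
                                            colour = p)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = c(r0_A, r0_B), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(title = "B: raised blow probability moves the minimiser right",
                  x = "startle magnitude r", y = "total cost") +
    base_theme

  opp_df <- function(eta) {
    f <- fam_eta(eta)
    data.frame(r = rep(r, 5),
               cost = c(f$fns$c_r_direct(r),
                        eta * f$fns$c_r_forgone(r),
                        p_for_eta * f$fns$c_b_direct(r),
                        p_for_eta * eta * f$fns$c_b_forgone(r),
                        total_cost(f, p_for_eta, r)),
               component = rep(c("startle direct", "startle opportunity",
                                 "blow direct (expected)",
                                 "blow opportunity (expected)", "total"),
                               each = length(r)))
  }
  p_C <- panel(opp_df(eta_pair[1]), r0_C,
               sprintf("C: direct and opportunity costs, eta = %g", eta_pair[1]))
  df_D <- rbind(cbind(opp_df(eta_pair[1]), eta = sprintf("eta = %g", eta_pair[1])),
                cbind(opp_df(eta_pair[2]), eta = sprintf("eta = %g", eta_pair[2])))
  df_D <- df_D[df_D$component == "total", ]
  p_D <- ggplot2::ggplot(df_D, ggplot2::aes(x = r, y = cost,
                                            colour = eta)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = c(r0_C, r0_D), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(title = "D: raised opportunity cost moves the minimiser right",
                  x = "startle magnitude r", y = "total cost") +
    base_theme

  plots <- list(A = p_A, B = p_B, C = p_C, D = p_D)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(plots)) {
      f <- file.path(out_dir, sprintf("panel_%s.%s", nm, format))
      ggplot2::ggsave(f, plots[[nm]], device = format, width = 5.5,
                      height = 4, dpi = 120)
      files <- c(files, f)
    }
    combined <- file.path(out_dir, paste0("cost_panels.", format))
    ggplot2::ggsave(combined,
                    patchwork::wrap_plots(p_A, p_B, p_C, p_D, ncol = 2),
                    device = format, width = 11, height = 8, dpi = 120)
    files <- c(files, combined)
  }
  invisible(list(r0_A = r0_A, r0_B = r0_B, r0_C = r0_C, r0_D = r0_D,
                 plots = plots, files = files))
}
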