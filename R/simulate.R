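#' Specification of a synthetic gradient-structured community
#'
#' Describes a synthetic dataset emulating a successional-gradient study:
#' plots at uniform positions along a gradient; zero-inflated
#' negative-binomial counts for bacterial and fungal variables;
#' logit-normal percent cover (0.1 resolution) for plants; smooth
#' monotone environmental measurements; and optional planted pairwise
#' links of known association class. Defaults mirror the emulated study
#' design: 135 plots and 1735 bacterial, 189 fungal, 30 plant, and 7
#' environmental variables.
#'
#' @param n_plots number of plots; default 135.
#' @param n_bacteria,n_fungi,n_plants,n_environment variables per group;
#'   defaults 1735, 189, 30, 7.
#' @param zero_inflation named per-group probability that a count is
#'   replaced by a structural zero; defaults 0.3 for microbes, 0
#'   otherwise.
#' @param nb_mean,nb_dispersion negative-binomial count model: mean scale
#'   and dispersion `d` (variance `mu + d mu^2`); defaults 100 and 0.5.
#' @param count_amplitude log-scale amplitude of the gradient response of
#'   count means; default 2.
#' @param cover_sd logit-scale noise of plant percent cover; default 0.5.
#' @param env_noise_sd Gaussian noise of environmental measurements
#'   (linear in the gradient); default 0.05.
#' @param response_probs probabilities of the per-taxon gradient response
#'   shapes `increasing`, `decreasing`, `optimum` (Gaussian optimum at a
#'   random position), `flat`.
#' @param links optional data.frame of planted links with columns `x`,
#'   `y` (variable names), `class` (`positive`, `negative`, `dome`,
#'   `sinusoid`, `none`), `effect` (> 0), `noise_sd`. The target `y` is
#'   regenerated as `effect * f(u) + noise`, where `u` is the rank
#'   percentile of `x` and `f` the class shape (dome: quadratic with
#'   interior optimum at 0.5; sinusoid: two full periods), then mapped
#'   back to the target's data kind.
#' @param link_count_scale count scale of link targets of kind `count`;
#'   default 100.
#' @param link_baseline baseline offset added to link-target latents
#'   before mapping to counts/cover; default 0.25. Keeps targets present
#'   where the planted function is low, so links modulate abundance
#'   rather than presence (otherwise the co-occurrence filter would clip
#'   the planted geometry asymmetrically).
#' @param seed integer seed; the dataset is a deterministic function of
#'   the spec.
#' @return a `synth_spec` object. Variable names are `b0001...`,
#'   `f001...`, `p01...`, `e1...` (available as `$variables`).
#' @export
synth_spec <- function(n_plots = 135, n_bacteria = 1735, n_fungi = 189,
                       n_plants = 30, n_environment = 7,
                       zero_inflation = c(Bacteria = 0.3, Fungi = 0.3,
                                          Plants = 0, Environment = 0),
                       nb_mean = 100, nb_dispersion = 0.5,
                       count_amplitude = 2, cover_sd = 0.5,
                       env_noise_sd = 0.05,
                       response_probs = c(increasing = 0.25,
                                          decreasing = 0.25,
                                          optimum = 0.35, flat = 0.15),
                       links = NULL, link_count_scale = 100,
                       link_baseline = 0.25, seed = 1) {
  stopifnot(n_plots >= 4, n_bacteria >= 0, n_fungi >= 0, n_plants >= 0,
            n_environment >= 0, nb_dispersion > 0)
  vars <- data.frame(
    variable = c(sprintf("b%04d", seq_len(n_bacteria)),
                 sprintf("f%03d", seq_len(n_fungi)),
                 sprintf("p%02d", seq_len(n_plants)),
                 sprintf("e%d", seq_len(n_environment))),
    group = rep(c("Bacteria", "Fungi", "Plants", "Environment"),
                c(n_bacteria, n_fungi, n_plants, n_environment)),
    kind = rep(c("count", "count", "cover", "measurement"),
               c(n_bacteria, n_fungi, n_plants, n_environment)),
    stringsAsFactors = FALSE)
  if (!is.null(links)) {
    need <- c("x", "y", "class", "effect", "noise_sd")
    if (!all(need %in% names(links)))
      stop("`links` needs columns: ", paste(need, collapse = ", "))
    bad <- setdiff(c(links$x, links$y), vars$variable)
    if (length(bad))
      stop("link references unknown variable(s): ",
           paste(bad, collapse = ", "))
    bad_cl <- setdiff(links$class,
                      c("positive", "negative", "dome", "sinusoid",
                        "none"))
    if (length(bad_cl))
      stop("unknown link class: ", paste(bad_cl, collapse = ", "))
    if (any(links$effect <= 0)) stop("link effect sizes must be > 0")
    if (anyDuplicated(links$y))
      stop("each link target may be planted only once")
  }
  structure(list(
    n_plots = n_plots, variables = vars,
    zero_inflation = zero_inflation, nb_mean = nb_mean,
    nb_dispersion = nb_dispersion, count_amplitude = count_amplitude,
    cover_sd = cover_sd, env_noise_sd = env_noise_sd,
    response_probs = response_probs, links = links,
    link_count_scale = link_count_scale, link_baseline = link_baseline,
    seed = seed),
    class = "synth_spec")
}

.link_shape <- function(class, u) {
  switch(class,
    positive = u,
    negative = 1 - u,
    dome = 1 - 4 * (u - 0.5)^2,
    # two full periods, phased so the shape is symmetric about u = 0.5:
    # a sine phased at 0 would correlate with u (covariance -1/(4*pi))
    sinusoid = (cos(4 * pi * u) + 1) / 2,
    stop("unknown link class: ", class))
}

#' Generate a synthetic community dataset
#'
#' Realizes a [synth_spec()]: the same spec (including its seed) always
#' yields the identical dataset. Environmental variables are linear in
#' the gradient with Gaussian noise; taxa follow their response shapes
#' through the count/cover observation models; planted links regenerate
#' the target variable as a function of the source's rank percentile
#' plus noise; per-group zero inflation is applied after the signal is
#' constructed.
#'
#' @param spec a [synth_spec()].
#' @return list with `table` (an [abundance_table()]) and `truth` (list
#'   with `links` — the planted links with their generating class — and
#'   `responses` — each variable's gradient response shape).
#' @export
synth_community <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_plots
  g <- (seq_len(n) - 0.5) / n
  plots <- sprintf("plot%03d", seq_len(n))
  vars <- spec$variables
  nv <- nrow(vars)
  shapes <- names(spec$response_probs)
  values <- matrix(0, n, nv, dimnames = list(plots, vars$variable))
  resp <- character(nv)
  zi_of <- function(grp) {
    z <- spec$zero_inflation[[grp]]
    if (is.null(z) || is.na(z)) 0 else z
  }
  for (j in seq_len(nv)) {
    kind <- vars$kind[j]
    if (kind == "measurement") {
      resp[j] <- if (stats::runif(1) < 0.5) "increasing" else "decreasing"
      slope <- (if (resp[j] == "increasing") 1 else -1) *
        stats::runif(1, 0.5, 1.5)
      values[, j] <- stats::runif(1) + slope * g +
        stats::rnorm(n, 0, spec$env_noise_sd)
      next
    }
    resp[j] <- sample(shapes, 1, prob = spec$response_probs)
    latent <- switch(resp[j],
      increasing = g,
      decreasing = 1 - g,
      optimum = {
        ctr <- stats::runif(1, 0.1, 0.9)
        wid <- stats::runif(1, 0.08, 0.3)
        exp(-(g - ctr)^2 / (2 * wid^2))
      },
      flat = rep(0.5, n))
    if (kind == "count") {
      mu <- spec$nb_mean * exp(spec$count_amplitude * (latent - 0.5))
      values[, j] <- stats::rnbinom(n, mu = mu,
                                    size = 1 / spec$nb_dispersion)
    } else {  # cover: logit-normal percent, 0.1 resolution
      p <- pmin(pmax(0.02 + 0.5 * latent, 0.001), 0.98)
      values[, j] <- round(
        100 * stats::plogis(stats::qlogis(p) +
                              stats::rnorm(n, 0, spec$cover_sd)), 1)
    }
    zi <- zi_of(vars$group[j])
    if (zi > 0)
      values[, j] <- values[, j] * stats::rbinom(n, 1, 1 - zi)
  }
  if (!is.null(spec$links)) {
    for (i in seq_len(nrow(spec$links))) {
      ln <- spec$links[i, ]
      if (ln$class == "none") next
      u <- rank(values[, ln$x], ties.method = "average") / n
      latent <- ln$effect * .link_shape(ln$class, u) +
        stats::rnorm(n, 0, ln$noise_sd)
      j <- match(ln$y, vars$variable)
      shifted <- latent + spec$link_baseline
      values[, j] <- switch(vars$kind[j],
        count = round(pmax(0, spec$link_count_scale * shifted)),
        cover = round(100 * pmin(pmax(shifted, 0) / 1.5, 1), 1),
        measurement = latent)
      zi <- zi_of(vars$group[j])
      if (zi > 0)
        values[, j] <- values[, j] * stats::rbinom(n, 1, 1 - zi)
    }
  }
  tbl <- abundance_table(values,
                         groups = stats::setNames(vars$group,
                                                  vars$variable),
                         gradient = stats::setNames(g, plots),
                         kind = stats::setNames(vars$kind,
                                                vars$variable))
  truth_links <- if (is.null(spec$links)) {
    data.frame(x = character(0), y = character(0), class = character(0),
               effect = numeric(0), noise_sd = numeric(0))
  } else spec$links
  list(table = tbl,
       truth = list(links = truth_links,
                    responses = data.frame(variable = vars$variable,
                                           response = resp,
                                           stringsAsFactors = FALSE)))
}

#' Small deterministic test community
#'
#' A 40-plot, 12-variable dataset (3 variables per constituent group)
#' with one planted link of each association class (positive, negative,
#' dome, sinusoid, none), used throughout the examples and tests. Fully
#' deterministic: repeated calls return the identical dataset.
#'
#' @return as [synth_community()].
#' @examples
#' fx <- fixture_small()
#' dim(fx$table)
#' fx$truth$links
#' @export
fixture_small <- function() {
  links <- data.frame(
    x = c("f001", "f002", "p01", "p02", "e1"),
    y = c("b0001", "b0002", "b0003", "f003", "p03"),
    class = c("positive", "negative", "dome", "sinusoid", "none"),
    effect = 1, noise_sd = 0.08, stringsAsFactors = FALSE)
  spec <- synth_spec(
    n_plots = 40, n_bacteria = 3, n_fungi = 3, n_plants = 3,
    n_environment = 3,
    zero_inflation = c(Bacteria = 0.1, Fungi = 0.1, Plants = 0,
                       Environment = 0),
    nb_mean = 150, nb_dispersion = 0.5, links = links, seed = 101)
  synth_community(spec)
}
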