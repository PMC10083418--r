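#' Build a run configuration
#'
#' Assembles and validates the blocks that drive
#' \code{\link{run_pipeline}}. Unknown keys in any block are rejected
#' with the offending key named, so configuration typos fail loudly.
#'
#' @param model named list with \code{a}, \code{b}, \code{c}, \code{d},
#'   \code{I}.
#' @param network named list: either \code{n_r}, \code{n_e}, \code{p},
#'   \code{seed} for generated layers, or \code{file_R}, \code{file_E},
#'   \code{format} for file-loaded layers.
#' @param diffusion named list with \code{du}, \code{dv} (optionally
#'   the four per-layer coefficients \code{du_R}, \code{du_E},
#'   \code{dv_R}, \code{dv_E}).
#' @param sim named list of \code{\link{sim_config}} arguments.
#' @param label optional run label recorded in the manifest.
#' @return A validated list of class \code{"fhn_run_config"}.
#' @export
run_config <- function(model = list(), network = list(), diffusion = list(),
                       sim = list(), label = NULL) {
  check_keys <- function(block, allowed, name) {
    extra <- setdiff(names(block), allowed)
    if (length(extra))
      stop(sprintf("unknown key '%s' in '%s' block", extra[1], name),
           call. = FALSE)
    block
  }
  model <- utils::modifyList(list(a = 1, b = 1, c = 2, d = 1, I = 0.7),
                             check_keys(model, c("a", "b", "c", "d", "I"),
                                        "model"))
  network <- check_keys(network,
                        c("n_r", "n_e", "p", "seed",
                          "file_R", "file_E", "format"), "network")
  network <- utils::modifyList(list(n_r = 20, n_e = 20, p = 0.01, seed = 1),
                               network)
  diffusion <- check_keys(diffusion,
                          c("du", "dv", "du_R", "du_E", "dv_R", "dv_E"),
                          "diffusion")
  diffusion <- utils::modifyList(list(du = 0, dv = 0), diffusion)
  sim <- check_keys(sim, names(formals(sim_config)), "sim")
  cfg <- list(model = model, network = network, diffusion = diffusion,
              sim = sim, label = label)
  # validate eagerly so malformed configs fail before any artifact exists
  do.call(fhn_model, model)
  do.call(diffusion_params, diffusion)
  do.call(sim_config, sim)
  structure(cfg, class = "fhn_run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return A validated \code{"fhn_run_config"}.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "'", call. = FALSE))
  do.call(run_config, raw[intersect(names(raw),
                                    c("model", "network", "diffusion",
                                      "sim", "label"))])
}

#' Preset parameter sets for the reference scenarios
#'
#' Returns the run configuration for one of the named simulation
#' scenarios studied with this model (base parameters \eqn{a = 1, b =
#' 1, c = 2, d = 1, I = 0.7}, two 20-node random layers,
#' \eqn{D_u = 0.01} unless the scenario sets diffusion to zero):
#' \describe{
#'   \item{fig3}{\eqn{D_v = 8}, \eqn{p = 0.01} (dispersion curve study).}
#'   \item{fig4a..fig4d}{\eqn{(D_v, p)} = (9, 0.001), (10, 0.006),
#'     (10, 0.01), (10, 0.1) (Turing onset sweep; fig5a..d are the
#'     same states, so these names are aliased).}
#'   \item{fig6a..fig6d}{the fig4a base state with noise amplitude
#'     \eqn{np} = 1e-7, 1e-6, 1e-4, 1e-3.}
#'   \item{fig7}{\eqn{D_u = D_v = 0}, delay \eqn{\tau = 0.6} just above
#'     the single-node Hopf threshold.}
#'   \item{fig9a..fig9d}{\eqn{D_v = 8} with \eqn{(\tau, p)} = (0.3,
#'     0.01), (1, 0.01), (1, 0.1), (1, 0.3) (delay/synchrony sweep).}
#' }
#'
#' @param name scenario name (see Details; \code{fig5a}..\code{fig5d}
#'   accepted as aliases of \code{fig4a}..\code{fig4d}).
#' @param seed seed for layer generation and simulation.
#' @return An \code{"fhn_run_config"}.
#' @examples
#' make_fixture("fig4c", seed = 7)$diffusion
#' @export
make_fixture <- function(name, seed = 1L) {
  name <- sub("^fig5", "fig4", name)
  presets <- list(
    fig3  = list(diffusion = list(du = 0.01, dv = 8), network = list(p = 0.01)),
    fig4a = list(diffusion = list(du = 0.01, dv = 9), network = list(p = 0.001)),
    fig4b = list(diffusion = list(du = 0.01, dv = 10), network = list(p = 0.006)),
    fig4c = list(diffusion = list(du = 0.01, dv = 10), network = list(p = 0.01)),
    fig4d = list(diffusion = list(du = 0.01, dv = 10), network = list(p = 0.1)),
    fig6a = list(diffusion = list(du = 0.01, dv = 9), network = list(p = 0.001),
                 sim = list(noise = 1e-7)),
    fig6b = list(diffusion = list(du = 0.01, dv = 9), network = list(p = 0.001),
                 sim = list(noise = 1e-6)),
    fig6c = list(diffusion = list(du = 0.01, dv = 9), network = list(p = 0.001),
                 sim = list(noise = 1e-4)),
    fig6d = list(diffusion = list(du = 0.01, dv = 9), network = list(p = 0.001),
                 sim = list(noise = 1e-3)),
    fig7  = list(diffusion = list(du = 0, dv = 0), sim = list(tau = 0.6)),
    fig9a = list(diffusion = list(du = 0.01, dv = 8), network = list(p = 0.01),
                 sim = list(tau = 0.3)),
    fig9b = list(diffusion = list(du = 0.01, dv = 8), network = list(p = 0.01),
                 sim = list(tau = 1)),
    fig9c = list(diffusion = list(du = 0.01, dv = 8), network = list(p = 0.1),
                 sim = list(tau = 1)),
    fig9d = list(diffusion = list(du = 0.01, dv = 8), network = list(p = 0.3),
                 sim = list(tau = 1)))
  if (!name %in% names(presets))
    stop("unknown scenario '", name, "'; known: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  pre <- presets[[name]]
  network <- utils::modifyList(list(seed = as.integer(seed)),
                               pre$network %||% list())
  sim <- utils::modifyList(list(seed = as.integer(seed),
                                init = "perturbed"),
                           pre$sim %||% list())
  run_config(model = list(), network = network,
             diffusion = pre$diffusion, sim = sim, label = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline and write artifacts
#'
#' Executes one stage or the whole chain -- equilibria and their local
#' stability, product-spectrum Turing classification, per-mode Hopf
#' thresholds, the normal form of the \eqn{\Lambda = 0} mode, and a
#' simulation -- writing CSV/JSON artifacts plus a manifest that
#' records the seed, a configuration hash, the package version and a
#' content hash of every file written. Stages that presume a stable
#' base state abort with an explanatory error if the equilibrium fails
#' the no-diffusion stability test.
#'
#' @param config an \code{"fhn_run_config"} (see \code{\link{run_config}},
#'   \code{\link{make_fixture}}).
#' @param command one of \code{"equilibrium"}, \code{"turing"},
#'   \code{"hopf"}, \code{"normalform"}, \code{"simulate"},
#'   \code{"full"}.
#' @param out_dir output directory (created if needed).
#' @param equilibrium equilibrium index for analyses (default 1).
#' @return Invisibly, the manifest as a list (also written to
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config, command = c("full", "equilibrium", "turing",
                                             "hopf", "normalform", "simulate"),
                         out_dir = ".", equilibrium = 1L) {
  stopifnot(inherits(config, "fhn_run_config"))
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  seed <- config$network$seed

  model <- do.call(fhn_model, config$model)
  diff <- do.call(diffusion_params, config$diffusion)
  lin <- linearize(model, equilibrium)

  stages <- if (command == "full")
    c("equilibrium", "turing", "hopf", "normalform", "simulate")
  else command

  layers <- NULL
  get_layers <- function() {
    if (is.null(layers)) {
      nw <- config$network
      layers <<- if (!is.null(nw$file_R))
        list(R = load_layer(nw$file_R, nw$format %||% "edge-list"),
             E = load_layer(nw$file_E, nw$format %||% "edge-list"))
      else
        list(R = generate_layer(nw$n_r, nw$p,
                                substream_seed(seed, "graph_R")),
             E = generate_layer(nw$n_e, nw$p,
                                substream_seed(seed, "graph_E")))
    }
    layers
  }
  need_h1 <- function(stage) {
    if (!check_h1(lin))
      stop("stage '", stage, "' aborted: the equilibrium is unstable ",
           "without diffusion, so diffusion/delay-driven instability ",
           "analyses are not meaningful", call. = FALSE)
  }
  results <- list()

  if ("equilibrium" %in% stages) {
    f <- file.path(out_dir, "equilibria.csv")
    df <- model$equilibria
    df$h1_stable <- vapply(seq_len(nrow(df)), function(i)
      check_h1(linearize(model, i)), logical(1))
    write_csv12(df, f)
    files <- c(files, f)
    results$equilibria <- df
  }
  if ("turing" %in% stages) {
    need_h1("turing")
    spec <- product_spectrum(get_layers()$R, get_layers()$E)
    ta <- classify_spectrum(lin, diff, spec)
    f <- file.path(out_dir, "dispersion.csv")
    write_csv12(ta$points[, c("lambda_R", "lambda_E", "lambda_sum",
                              "h2", "unstable")], f)
    fj <- file.path(out_dir, "turing_summary.json")
    du <- diff$du_R
    jsonlite::write_json(list(
      any_unstable = ta$any_unstable, n_unstable = ta$n_unstable,
      window = ta$window,
      critical_dv_continuous = if (lin$a11 > 0 && du > 0)
        critical_dv(lin, du) else NULL,
      critical_dv_network = if (du > 0)
        network_critical_dv(lin, du, spec) else NULL),
      fj, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, f, fj)
    results$turing <- ta
  }
  if ("hopf" %in% stages) {
    need_h1("hopf")
    spec <- product_spectrum(get_layers()$R, get_layers()$E)
    hs <- tau0_over_spectrum(lin, diff, spec)
    f <- file.path(out_dir, "hopf_modes.csv")
    write_csv12(hs$table, f)
    fj <- file.path(out_dir, "hopf_summary.json")
    jsonlite::write_json(list(tau0 = hs$tau0_min,
                              critical_mode = hs$critical_mode),
                         fj, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, f, fj)
    results$hopf <- hs
  }
  if ("normalform" %in% stages) {
    need_h1("normalform")
    nf <- normal_form(lin, diff = diff)
    f <- file.path(out_dir, "normal_form.json")
    jsonlite::write_json(normal_form_json(nf), f,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    results$normal_form <- nf
  }
  if ("simulate" %in% stages) {
    cfg <- do.call(sim_config, config$sim)
    tr <- fhn_simulate(model, get_layers(), diff, cfg, equilibrium)
    f1 <- file.path(out_dir, "summary.csv")
    write_csv12(data.frame(time = tr$times,
                           mean_u = colMeans(tr$u),
                           std_u = apply(tr$u, 2, stats::sd)), f1)
    f2 <- file.path(out_dir, "pattern.csv")
    pm <- pattern_matrix(tr, sort_nodes = TRUE)
    utils::write.table(signif(pm, 12), f2, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f1, f2)
    results$synchrony <- tryCatch(synchrony_index(tr),
                                  warning = function(w) 1)
  }

  manifest <- list(
    package = "fhnnet",
    version = as.character(utils::packageVersion("fhnnet")),
    command = command,
    label = config$label,
    seed = seed,
    config = unclass(config),
    config_hash = config_hash(config),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) list(path = f,
                                    md5 = unname(tools::md5sum(f)))))
  if (!is.null(results$synchrony))
    manifest$synchrony <- results$synchrony
  if (!is.null(results$hopf))
    manifest$tau0 <- results$hopf$tau0_min
  if (!is.null(results$normal_form))
    manifest$classification <-
      unname(results$normal_form$classification["direction"])
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(results, list(manifest = manifest)))
}

# all numeric CSV output at 12 significant digits (byte-stable text)
write_csv12 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

cplx <- function(z) list(re = Re(z), im = Im(z))

normal_form_json <- function(nf) {
  list(variant = nf$variant,
       omega0 = nf$omega0, tau0 = nf$tau0,
       q2 = cplx(nf$eigvectors$q2), q1_star = cplx(nf$eigvectors$q1_star),
       kappa = cplx(nf$eigvectors$kappa),
       g20 = cplx(nf$g20), g11 = cplx(nf$g11), g02 = cplx(nf$g02),
       g21 = cplx(nf$g21),
       ell1 = lapply(nf$ell1, cplx), ell2 = lapply(nf$ell2, cplx),
       W20_0 = lapply(nf$W20_0, cplx), W11_0 = lapply(nf$W11_0, cplx),
       c1_0 = cplx(nf$c1_0), dlambda_dtau = cplx(nf$dlambda_dtau),
       mu2 = nf$mu2, beta2 = nf$beta2, T2 = nf$T2,
       classification = as.list(nf$classification))
}
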