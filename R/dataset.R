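#' @keywords internal
"_PACKAGE"

TRAITS <- c("fy", "fl", "nrps")

#' Trait names handled by the pipeline
#'
#' The three banana traits measured in the packaged trial: fruit yield
#' (`fy`, kg/plant), fruit length (`fl`, cm) and number of rows per spike
#' (`nrps`, count). Trait arguments throughout the package accept these
#' codes case-insensitively.
#'
#' @return Character vector of trait codes.
#' @export
trait_names <- function() TRAITS

match_trait <- function(trait) {
  t <- tolower(as.character(trait)[1])
  if (!t %in% TRAITS) {
    stop("unknown trait '", trait, "'; expected one of: ",
         paste(TRAITS, collapse = ", "), call. = FALSE)
  }
  t
}

#' Construct a fertilizer dose triple
#'
#' @param n_g,k_g,mg_g grams of nitrogen, potassium and magnesium per plant.
#'   Must be finite and non-negative.
#' @return A named numeric vector of class `fertilizer_levels`.
#' @export
fertilizer_levels <- function(n_g, k_g, mg_g) {
  x <- c(n_g = as.numeric(n_g), k_g = as.numeric(k_g), mg_g = as.numeric(mg_g))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("fertilizer doses must be finite and >= 0", call. = FALSE)
  }
  class(x) <- "fertilizer_levels"
  x
}

TABLE_COLS <- c("n_g", "k_g", "mg_g",
                "fy_mean", "fy_sem", "fl_mean", "fl_sem",
                "nrps_mean", "nrps_sem")

new_trait_table <- function(records, replicates = NULL, provenance = list()) {
  stopifnot(is.data.frame(records))
  records$n_reps <- if (is.null(records$n_reps)) 3L else as.integer(records$n_reps)
  structure(list(records = records,
                 replicates = replicates,
                 provenance = provenance),
            class = "trait_table")
}

validate_trait_table <- function(tab, factorial = TRUE) {
  rec <- tab$records
  missing_cols <- setdiff(TABLE_COLS, names(rec))
  if (length(missing_cols) > 0) {
    stop("trait table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keys <- paste(rec$n_g, rec$k_g, rec$mg_g)
  if (anyDuplicated(keys)) stop("duplicated treatment level triples", call. = FALSE)
  sems <- as.matrix(rec[paste0(TRAITS, "_sem")])
  if (any(sems < 0) || any(!is.finite(sems))) {
    stop("SEMs must be finite and >= 0", call. = FALSE)
  }
  if (factorial) {
    grid <- expand.grid(n_g = sort(unique(rec$n_g)),
                        k_g = sort(unique(rec$k_g)),
                        mg_g = sort(unique(rec$mg_g)))
    if (nrow(rec) != nrow(grid) ||
        !all(paste(grid$n_g, grid$k_g, grid$mg_g) %in% keys)) {
      stop("treatments do not form a complete full factorial grid", call. = FALSE)
    }
  }
  invisible(tab)
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Factorial fertilizer trial:", nrow(x$records), "treatments")
  if (!is.null(x$replicates)) {
    cat(",", nrow(x$replicates), "replicate records")
  }
  cat("\n  N levels: ", paste(sort(unique(x$records$n_g)), collapse = "/"),
      " g; K: ", paste(sort(unique(x$records$k_g)), collapse = "/"),
      " g; Mg: ", paste(sort(unique(x$records$mg_g)), collapse = "/"), " g\n",
      sep = "")
  invisible(x)
}

#' Load the packaged banana fertilizer trial
#'
#' Reads the packaged dataset of a greenhouse banana (Grand Nain) trial on a
#' full 3 x 4 x 3 factorial of N (0/100/200 g), K (0/100/200/300 g) and
#' Mg (0/50/100 g) per plant: 36 treatment means with standard errors over
#' 3 replications for fruit yield (kg/plant), fruit length (cm) and number
#' of rows per spike.
#'
#' @param path Optional path to a CSV with the same schema
#'   (`n_g,k_g,mg_g,fy_mean,fy_sem,fl_mean,fl_sem,nrps_mean,nrps_sem`),
#'   for loading user experiments. Defaults to the packaged fixture.
#' @param factorial Require a complete full-factorial grid (default `TRUE`).
#' @return A `trait_table` with 36 records (one per treatment).
#' @export
load_table1 <- function(path = NULL, factorial = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "banana_fertilizer_trials.csv",
                        package = "grnnga")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("trial data file not found: '", path, "'", call. = FALSE)
  }
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- new_trait_table(rec, provenance = list(fixture = path))
  validate_trait_table(tab, factorial = factorial)
  tab
}

#' Write a trait table back to the loader's CSV schema
#'
#' @param table a `trait_table`
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(table$records[TABLE_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Treatment with the highest mean for a trait
#'
#' Ties are broken toward the lowest (N, K, Mg) triple in lexicographic
#' order so the answer is deterministic.
#'
#' @param table a `trait_table`
#' @param trait one of `"fy"`, `"fl"`, `"nrps"`
#' @return list with `levels` (a [fertilizer_levels()]) and `value`
#'   (the treatment mean in trait units).
#' @export
argmax_trait <- function(table, trait) {
  trait <- match_trait(trait)
  rec <- table$records
  m <- rec[[paste0(trait, "_mean")]]
  ord <- order(-m, rec$n_g, rec$k_g, rec$mg_g)
  top <- rec[ord[1], ]
  list(levels = fertilizer_levels(top$n_g, top$k_g, top$mg_g),
       value = m[ord[1]])
}

#' Reconstruct replicate-level observations from means and SEMs
#'
#' The packaged trial publishes only treatment means +/- SEM over `n_reps`
#' replications. Model fitting, however, targets replicate-level data. For
#' each treatment and trait this draws `n_reps` values from
#' N(mean, (SEM * sqrt(n_reps))^2) and then recenters/rescales the draw so
#' that its sample mean equals the printed mean exactly and its sample SD
#' equals SEM * sqrt(n_reps) exactly (the identity SD = SEM * sqrt(r)).
#' Treatments with SEM = 0 yield `n_reps` copies of the mean.
#'
#' @param table a `trait_table`
#' @param seed integer seed; the reconstruction is deterministic given it.
#' @param n_reps replicates per treatment (>= 2), default 3.
#' @return The table with a `$replicates` data frame added: one row per
#'   treatment x replicate, columns `n_g,k_g,mg_g,rep,fy,fl,nrps` plus the
#'   treatment index.
#' @export
reconstruct_replicates <- function(table, seed, n_reps = 3L) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 2) stop("n_reps must be >= 2 to carry an SEM", call. = FALSE)
  rec <- table$records
  n_t <- nrow(rec)
  out <- data.frame(
    treatment = rep(seq_len(n_t), each = n_reps),
    n_g = rep(rec$n_g, each = n_reps),
    k_g = rep(rec$k_g, each = n_reps),
    mg_g = rep(rec$mg_g, each = n_reps),
    rep = rep(seq_len(n_reps), times = n_t)
  )
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  for (tr in TRAITS) {
    mu <- rec[[paste0(tr, "_mean")]]
    sdv <- rec[[paste0(tr, "_sem")]] * sqrt(n_reps)
    vals <- numeric(n_t * n_reps)
    for (i in seq_len(n_t)) {
      z <- stats::rnorm(n_reps)
      s <- stats::sd(z)
      # moment correction: exact sample mean/SD (degenerate draws left centered)
      z <- if (s > 0) (z - mean(z)) / s else rep(0, n_reps)
      vals[(i - 1L) * n_reps + seq_len(n_reps)] <- mu[i] + sdv[i] * z
    }
    out[[tr]] <- vals
  }
  table$replicates <- out
  table$provenance$replicate_seed <- seed
  table
}

# Seed scoping without touching the caller's RNG stream.
local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
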