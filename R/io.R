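# Sample-table I/O (decimal point or decimal comma), network export, and the
# end-to-end pipeline from CSV to report bundle.

#' Read an oil sample table from CSV
#'
#' Reads a comma-separated sample table with columns `sample_id`, `region`,
#' `extraction` and the four fatty-acid percentages. Numeric fields written
#' with a decimal comma (`"24,24"`), including stray spaces after the comma
#' as they occur in typeset tables, are parsed transparently. Every row's
#' profile is range-checked and its compositional closure assessed.
#'
#' Published literature compositions often list only the four major acids and
#' omit minors, so their sums can fall a point or two short of 100. By
#' default a closure deviation beyond `tol` therefore raises a warning naming
#' the rows; set `closure = "error"` to reject such rows instead.
#'
#' @param path Path to the CSV file.
#' @param tol Closure tolerance (percentage points on the profile sum).
#' @param acids Fatty-acid column names expected in the file.
#' @param closure How to treat a closure deviation beyond `tol`: `"warn"`
#'   (default) or `"error"`.
#' @return Data frame of validated samples.
#' @export
read_samples <- function(path, tol = 1.0,
                         acids = c("palmitic", "stearic", "oleic", "linoleic"),
                         closure = c("warn", "error")) {
  closure <- match.arg(closure)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path,
    stringsAsFactors = FALSE, colClasses = "character",
    check.names = FALSE, strip.white = TRUE
  )
  required <- c("sample_id", "region", "extraction", acids)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- setdiff(names(raw), c("sample_id", "region", "extraction"))
  for (col in numeric_cols) {
    parsed <- parse_decimal(raw[[col]])
    bad <- which(is.na(parsed) & nzchar(trimws(raw[[col]])))
    if (length(bad) > 0) {
      stop(
        sprintf(
          "unparseable numeric value '%s' (row %d, column '%s')",
          raw[[col]][bad[1]], bad[1], col
        ),
        call. = FALSE
      )
    }
    raw[[col]] <- parsed
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicate sample_id: ",
      paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  open_rows <- character(0)
  for (i in seq_len(nrow(raw))) {
    prof <- stats::setNames(as.numeric(raw[i, acids]), acids)
    # range check always errors; closure handled per the 'closure' policy
    tryCatch(validate_profile(prof, tol = Inf), error = function(e) {
      stop("row ", i, " (", raw$sample_id[i], "): ", conditionMessage(e),
        call. = FALSE
      )
    })
    if (abs(sum(prof) - 100) > tol) {
      msg <- sprintf("%s (sum %.2f)", raw$sample_id[i], sum(prof))
      if (closure == "error") {
        stop("row ", i, ": closure violation: ", msg, call. = FALSE)
      }
      open_rows <- c(open_rows, msg)
    }
  }
  if (length(open_rows) > 0) {
    warning(
      "profile sum outside 100 ± ", tol, " for: ",
      paste(open_rows, collapse = ", "),
      " (minor acids presumably omitted)",
      call. = FALSE
    )
  }
  raw
}

# "24,24" / "13, 84" / "24.24" -> 24.24
parse_decimal <- function(x) {
  x <- gsub("[[:space:] ]", "", as.character(x))
  suppressWarnings(as.numeric(sub(",", ".", x, fixed = TRUE)))
}

#' Write a sample table in the dialect [read_samples()] reads
#'
#' @param samples Sample data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export a network to DOT, GraphML or adjacency CSV
#'
#' DOT output is a Graphviz digraph: directed arcs carry an arrowhead,
#' undirected tie edges are emitted with `dir=none`; every edge is annotated
#' with its partial correlation and orientation ratio B. GraphML export goes
#' through igraph with `pcorr`, `B` and `directed` edge attributes. The
#' adjacency CSV holds one row per edge (`from`, `to`, `pcorr`, `B`,
#' `directed`) plus all node names, and round-trips through
#' [read_network_csv()].
#'
#' @param net An `oil_network` from [build_network()] / [orient_edges()].
#' @param path Output file path.
#' @param format `"dot"`, `"graphml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("dot", "graphml", "csv")) {
  stopifnot(inherits(net, "oil_network"))
  format <- tryCatch(match.arg(format),
    error = function(e) {
      stop("unknown network format: ", format[1], call. = FALSE)
    }
  )
  switch(format,
    dot = {
      lines <- c(
        "digraph oil_network {",
        sprintf("  \"%s\";", net$nodes),
        if (nrow(net$edges) > 0) {
          sprintf(
            "  \"%s\" -> \"%s\" [label=\"rho=%.3f B=%.3f\"%s];",
            net$edges$from, net$edges$to, net$edges$pcorr, net$edges$B,
            ifelse(net$edges$directed, "", " dir=none")
          )
        },
        "}"
      )
      writeLines(lines, path)
    },
    graphml = {
      ig <- igraph::graph_from_data_frame(
        net$edges[, c("from", "to", "pcorr", "B", "directed")],
        directed = TRUE, vertices = net$nodes
      )
      igraph::write_graph(ig, path, format = "graphml")
    },
    csv = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(paste0("# nodes: ", paste(net$nodes, collapse = ";")), con)
      utils::write.csv(
        net$edges[, c("from", "to", "pcorr", "B", "directed")],
        con,
        row.names = FALSE
      )
    }
  )
  invisible(path)
}

#' Read a network adjacency CSV back
#'
#' Inverse of [export_network()]'s CSV format.
#'
#' @param path Path written by `export_network(..., format = "csv")`.
#' @return An `oil_network` (without precision-estimate audit components).
#' @export
read_network_csv <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# nodes: ")) {
    stop("not a network adjacency CSV (missing node header): ", path,
      call. = FALSE
    )
  }
  nodes <- strsplit(sub("^# nodes: ", "", header), ";", fixed = TRUE)[[1]]
  edges <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  edges$directed <- as.logical(edges$directed)
  structure(
    list(nodes = nodes, edges = edges, g = NULL, tie_eps = NA_real_),
    class = "oil_network"
  )
}

#' Run the full analysis pipeline on a sample table
#'
#' Reads (or accepts) a sample table, appends the derived nutritional
#' indices, computes quality indices when raw titration/absorbance columns
#' are present, runs the Pearson correlation screen, builds the
#' partial-correlation network, and writes the report bundle to `out_dir`:
#' `indices.csv`, optional `quality.csv`, `correlation_r.csv`,
#' `correlation_p.csv`, `correlations_tidy.csv`, `network.csv`,
#' `network.dot`, `network.graphml` and `run_log.txt` (configuration echo,
#' package version and config hash). The run is deterministic given input,
#' configuration and seed.
#'
#' Raw quality columns recognised: `V_naoh_ml`, `C_naoh`, `mass_g`
#' (free acidity); `V_koh_ml`, `N_koh`, `mass_koh_g` (acid index); `A630`,
#' `A670`, `A710`, `A470`, `A725`, `path_cm` (contents).
#'
#' @param input Path to a sample CSV, or a sample data frame.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param tau,lambda,tie_eps Network parameters, see [build_network()].
#' @param encoding Categorical coding, see [default_encoding()].
#' @param bands Grade bands, see [grade_bands()].
#' @param alpha Significance levels for the correlation stars.
#' @param adjust P-value adjustment method, see [pearson_with_pvalues()].
#' @param seed Integer seed recorded with the run (the analysis itself is
#'   deterministic; the seed matters when the input is itself simulated).
#' @return A list of class `report_bundle`: `samples` (with indices),
#'   `quality` (or `NULL`), `correlation`, `network`, `config`,
#'   `config_hash`, `files`.
#' @export
#' @examples
#' bundle <- run_pipeline(argan_oils(), out_dir = NULL)
#' bundle$network
run_pipeline <- function(input, out_dir = NULL, tau = 0.3, lambda = NULL,
                         tie_eps = 1e-9, encoding = default_encoding(),
                         bands = grade_bands(), alpha = c(0.05, 0.01),
                         adjust = "none", seed = 1) {
  samples <- if (is.character(input)) read_samples(input) else as.data.frame(input)
  samples <- with_stage("indices", add_derived_indices(samples))

  quality <- NULL
  if (all(c("V_naoh_ml", "C_naoh", "mass_g") %in% names(samples))) {
    quality <- with_stage("quality", {
      fa <- mapply(free_acidity, samples$V_naoh_ml, samples$C_naoh, samples$mass_g)
      q <- data.frame(
        sample_id = samples$sample_id, free_acidity = fa,
        grade = classify_grade(fa, bands), stringsAsFactors = FALSE
      )
      if (all(c("V_koh_ml", "N_koh", "mass_koh_g") %in% names(samples))) {
        q$acid_index <- mapply(
          acid_index, samples$V_koh_ml, samples$N_koh, samples$mass_koh_g
        )
      }
      if ("A725" %in% names(samples)) {
        q$polyphenol <- total_polyphenols(samples$A725)
      }
      if (all(c("A630", "A670", "A710") %in% names(samples))) {
        path_cm <- if ("path_cm" %in% names(samples)) samples$path_cm else 1
        q$chlorophyll <- mapply(
          chlorophyll_content, samples$A670, samples$A630, samples$A710, path_cm
        )
      }
      if ("A470" %in% names(samples)) {
        q$carotenoid <- carotenoid_content(samples$A470)
      }
      q
    })
  }

  X <- with_stage("encode", encode_samples(samples, encoding))
  correlation <- with_stage(
    "correlation",
    pearson_with_pvalues(X, alpha = alpha, adjust = adjust)
  )
  network <- with_stage(
    "network",
    build_network(X, tau = tau, lambda = lambda, tie_eps = tie_eps)
  )

  config <- list(
    input = if (is.character(input)) input else "<data frame>",
    tau = tau, lambda = if (is.null(lambda)) "auto" else lambda,
    tie_eps = tie_eps, encoding = encoding, alpha = alpha, adjust = adjust,
    seed = seed,
    version = as.character(utils::packageVersion("arganet"))
  )
  config_hash <- hash_config(config)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(out_dir, name)
    num2 <- function(df) {
      df[] <- lapply(df, function(c) if (is.numeric(c)) round(c, 2) else c)
      df
    }
    utils::write.csv(num2(samples), out("indices.csv"), row.names = FALSE)
    files <- out("indices.csv")
    if (!is.null(quality)) {
      utils::write.csv(num2(quality), out("quality.csv"), row.names = FALSE)
      files <- c(files, out("quality.csv"))
    }
    utils::write.csv(round(correlation$r, 3), out("correlation_r.csv"))
    utils::write.csv(round(correlation$p, 3), out("correlation_p.csv"))
    tidy <- correlation_tidy(correlation)
    tidy$r <- round(tidy$r, 3)
    tidy$p <- round(tidy$p, 3)
    utils::write.csv(tidy, out("correlations_tidy.csv"), row.names = FALSE)
    export_network(network, out("network.csv"), "csv")
    export_network(network, out("network.dot"), "dot")
    export_network(network, out("network.graphml"), "graphml")
    files <- c(
      files, out("correlation_r.csv"), out("correlation_p.csv"),
      out("correlations_tidy.csv"), out("network.csv"), out("network.dot"),
      out("network.graphml")
    )
    log_lines <- c(
      paste0("arganet ", config$version),
      paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
      paste0("config hash: ", config_hash),
      paste0(
        "config: ",
        paste(deparse(config[setdiff(names(config), "version")]),
          collapse = " "
        )
      ),
      sprintf("samples: %d, variables: %d", nrow(X), ncol(X)),
      sprintf(
        "network: lambda = %.6f, %d edge(s)",
        network$precision$lambda, nrow(network$edges)
      )
    )
    writeLines(log_lines, out("run_log.txt"))
    files <- c(files, out("run_log.txt"))
  }

  structure(
    list(
      samples = samples, quality = quality, correlation = correlation,
      network = network, config = config, config_hash = config_hash,
      files = files
    ),
    class = "report_bundle"
  )
}

# md5 of the canonicalized (deparsed) configuration
hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

# attach the failing stage's name to any propagated error
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Argan-oil analysis bundle\n")
  cat(sprintf("  samples: %d\n", nrow(x$samples)))
  cat(sprintf("  quality table: %s\n", if (is.null(x$quality)) "absent (no raw readings)" else "present"))
  cat(sprintf("  config hash: %s\n", x$config_hash))
  print(x$network)
  invisible(x)
}
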