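#' Tool specifications and the tool registry
#'
#' A tool specification declares the tool's data in/out ports, its default
#' parameter values, and how to invoke it: either a `command` template
#' rendered to an argv vector and run as a subprocess, or a `fun` — an R
#' function `function(inputs, params)` taking named input payload strings
#' and returning named output payload strings — executed in-process
#' (used by the deterministic stub suite). Command templates use
#' placeholders `{in:port}`, `{out:port}` and `{param:name}`.
#'
#' @param id Tool identifier.
#' @param in_ports,out_ports Character vectors of port names or lists of
#'   [wf_port()].
#' @param command Command template string (whitespace-separated argv
#'   tokens; placeholders are substituted within each token).
#' @param fun In-process implementation function.
#' @param params Named list of default parameter values.
#' @param locality `"local"` or `"remote"`.
#' @return `wf_tool()` returns a `wf_tool` object; `wf_registry()` returns
#'   a named list of tools usable wherever a registry is expected.
#' @examples
#' wf_tool("copy", "in", "out", command = "cp {in:in} {out:out}")
#' @export
wf_tool <- function(id, in_ports = character(0), out_ports = "out",
                    command = NULL, fun = NULL, params = list(),
                    locality = "local") {
  as_ports <- function(p) {
    if (is.character(p)) p <- lapply(p, wf_port)
    lapply(p, function(q) if (inherits(q, "wf_port")) q else do.call(wf_port, q))
  }
  if (is.null(command) && is.null(fun)) {
    wf_stop("TOOL_SPEC", sprintf("tool '%s': needs a command template or a function", id))
  }
  tool <- structure(list(id = id, in_ports = as_ports(in_ports),
                         out_ports = as_ports(out_ports), command = command,
                         fun = fun, params = params, locality = locality),
                    class = "wf_tool")
  if (!is.null(command)) check_template(tool)
  tool
}

#' @export
print.wf_tool <- function(x, ...) {
  cat(sprintf("<wf_tool '%s' in=[%s] out=[%s] %s>\n", x$id,
              paste(port_names(x$in_ports), collapse = ","),
              paste(port_names(x$out_ports), collapse = ","),
              if (is.null(x$command)) "builtin" else x$command))
  invisible(x)
}

#' @rdname wf_tool
#' @param ... `wf_tool` objects.
#' @export
wf_registry <- function(...) {
  tools <- list(...)
  names(tools) <- vapply(tools, `[[`, character(1), "id")
  structure(tools, class = "wf_registry")
}

registry_get <- function(registry, id) {
  if (is.null(registry)) return(NULL)
  registry[[id]]
}

#' Read a tool specification from a JSON document
#'
#' One JSON document per tool: fields `id`, `in_ports`, `out_ports`
#' (names or `{name, role}` objects), `command`, `params`, `locality`.
#'
#' @param path Path to the JSON tool document.
#' @return A `wf_tool`.
#' @export
wf_load_tool <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("id")) {
    if (is.null(doc[[f]])) wf_format_stop("SCHEMA", sprintf("tool document: missing '%s'", f))
  }
  ports <- function(x) lapply(x %||% list(), function(p) {
    if (is.character(p)) wf_port(p) else wf_port(p$name, p$role %||% "data")
  })
  wf_tool(doc$id, in_ports = ports(doc$in_ports), out_ports = ports(doc$out_ports),
          command = doc$command, params = doc$params %||% list(),
          locality = doc$locality %||% "local")
}

placeholders <- function(template) {
  m <- gregexpr("\\{(in|out|param):[^}]+\\}", template)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(template, gregexpr("\\{(in|out|param):[^}]+\\}", template))[[1]]
}

check_template <- function(tool) {
  ph <- placeholders(tool$command)
  for (p in ph) {
    inner <- sub("^\\{([a-z]+):(.+)\\}$", "\\1 \\2", p)
    parts <- strsplit(inner, " ", fixed = TRUE)[[1]]
    kind <- parts[1]; nm <- parts[2]
    ok <- switch(kind,
      "in" = nm %in% port_names(tool$in_ports),
      "out" = nm %in% port_names(tool$out_ports),
      "param" = TRUE)
    if (!ok) {
      wf_stop("TEMPLATE", sprintf("tool '%s': placeholder %s names an undeclared port",
                                  tool$id, p))
    }
  }
  invisible(tool)
}

#' Render a tool command template to a concrete command binding
#'
#' Substitutes `{in:port}`, `{out:port}` and `{param:name}` placeholders
#' and splits the template on whitespace into an argv vector — arguments
#' are passed to the process as a vector, never through a shell, so shell
#' metacharacters in payloads are inert. Every declared out-port gets a
#' reserved output path under `workdir`.
#'
#' @param tool A `wf_tool` with a command template.
#' @param input_files Named character vector/list: in-port -> staged path.
#' @param params Named list of effective parameter values.
#' @param workdir Instance working directory.
#' @return A list with `argv`, `input_files`, `output_files`, `workdir`.
#' @export
wf_render_command <- function(tool, input_files, params, workdir) {
  if (is.null(tool$command)) {
    wf_stop("TEMPLATE", sprintf("tool '%s' has no command template", tool$id))
  }
  output_files <- stats::setNames(
    file.path(workdir, paste0(port_names(tool$out_ports), ".out")),
    port_names(tool$out_ports))
  words <- strsplit(tool$command, "[[:space:]]+")[[1]]
  words <- words[nzchar(words)]
  argv <- vapply(words, function(w) {
    for (p in placeholders(w)) {
      parts <- strsplit(sub("^\\{(.+)\\}$", "\\1", p), ":", fixed = TRUE)[[1]]
      kind <- parts[1]; nm <- paste(parts[-1], collapse = ":")
      val <- switch(kind,
        "in" = input_files[[nm]],
        "out" = output_files[[nm]],
        "param" = params[[nm]])
      if (is.null(val)) {
        wf_stop("TEMPLATE", sprintf("unresolved placeholder %s for tool '%s'", p, tool$id))
      }
      w <- sub(p, as.character(val), w, fixed = TRUE)
    }
    if (grepl("\\{(in|out|param):", w)) {
      wf_stop("TEMPLATE", sprintf("unresolved placeholder in '%s'", w))
    }
    w
  }, character(1), USE.NAMES = FALSE)
  list(argv = argv, input_files = input_files,
       output_files = output_files, workdir = workdir)
}
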