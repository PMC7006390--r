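# Self-contained interactive HTML export: the node/edge document plus seeded
# layout positions are embedded as a JSON payload inside the page, and a
# small inline SVG viewer provides pan/zoom/select. No external assets are
# fetched at render or view time, so the file is hermetic and diffable.

html_payload_open <- '<script type="application/json" id="network-data">'
html_payload_close <- "</script>"

document_payload <- function(doc) {
  pos <- document_layout(doc)
  nodes <- dplyr::left_join(doc$nodes, pos, by = "id")
  nodes$color <- unname(doc$palette[nodes$color_key])
  payload <- list(
    layout_seed = doc$layout_seed,
    nodes = nodes,
    edges = doc$edges,
    palette = as.list(doc$palette)
  )
  as.character(jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA, na = "null"))
}

#' Render a network document as a self-contained interactive HTML file
#'
#' Embeds the node/edge data (with seeded layout positions) as a JSON
#' payload in a single HTML page with an inline SVG viewer supporting pan,
#' zoom and node selection. Rendering is deterministic: the same document
#' and layout seed produce a byte-identical embedded payload.
#'
#' @param doc A [to_document()] result.
#' @param path Output `.html` file path.
#' @return `path`, invisibly.
#' @export
render_html <- function(doc, path) {
  if (!inherits(doc, "network_document")) {
    abort_input("`doc` must come from to_document()")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_io(sprintf("output directory '%s' does not exist", dir))
  }
  payload <- document_payload(doc)
  notice <- if (nrow(doc$nodes) == 0) {
    '<p class="empty-note">This network is empty: no nodes to draw.</p>'
  } else {
    ""
  }
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>pathway network</title>\n",
    "<style>\n",
    "body{font-family:sans-serif;margin:0}\n",
    "#viz{width:100vw;height:92vh;cursor:grab}\n",
    "#info{padding:4px 10px;font-size:13px;color:#333}\n",
    ".empty-note{padding:2em;color:#666}\n",
    "</style>\n</head>\n<body>\n",
    "<div id=\"info\">drag to pan, scroll to zoom, click a node to inspect</div>\n",
    notice,
    html_payload_open, payload, html_payload_close, "\n",
    "<svg id=\"viz\"></svg>\n",
    "<script>\n", html_viewer_js(), "\n</script>\n",
    "</body>\n</html>\n"
  )
  ok <- tryCatch({ writeLines(html, path, sep = ""); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write HTML to '%s'", path))
  invisible(path)
}

html_viewer_js <- function() {
  paste(
    "var data = JSON.parse(document.getElementById('network-data').textContent);",
    "var svg = document.getElementById('viz');",
    "var NS = 'http://www.w3.org/2000/svg';",
    "var g = document.createElementNS(NS, 'g'); svg.appendChild(g);",
    "var tx = 400, ty = 300, scale = 40;",
    "function apply(){g.setAttribute('transform','translate('+tx+','+ty+') scale('+scale+')');}",
    "var byId = {};",
    "data.nodes.forEach(function(n){byId[n.id]=n;});",
    "data.edges.forEach(function(e){",
    "  var a=byId[e.from], b=byId[e.to]; if(!a||!b) return;",
    "  var l=document.createElementNS(NS,'line');",
    "  l.setAttribute('x1',a.x); l.setAttribute('y1',a.y);",
    "  l.setAttribute('x2',b.x); l.setAttribute('y2',b.y);",
    "  l.setAttribute('stroke','#bbb'); l.setAttribute('stroke-width',0.02);",
    "  g.appendChild(l);});",
    "data.nodes.forEach(function(n){",
    "  var s;",
    "  if(n.shape==='diamond'){",
    "    s=document.createElementNS(NS,'rect');",
    "    s.setAttribute('x',n.x-0.12); s.setAttribute('y',n.y-0.12);",
    "    s.setAttribute('width',0.24); s.setAttribute('height',0.24);",
    "    s.setAttribute('transform','rotate(45 '+n.x+' '+n.y+')');",
    "  } else {",
    "    s=document.createElementNS(NS,'circle');",
    "    s.setAttribute('cx',n.x); s.setAttribute('cy',n.y); s.setAttribute('r',0.1);",
    "  }",
    "  s.setAttribute('fill',n.color); s.setAttribute('stroke','#444');",
    "  s.setAttribute('stroke-width',0.01);",
    "  s.addEventListener('click',function(){",
    "    document.getElementById('info').textContent =",
    "      n.kind+' '+n.id+' ('+n.label+')'+(n.level?', level '+n.level:'')+(n.bin?', bin '+n.bin:'');",
    "  });",
    "  g.appendChild(s);",
    "  var t=document.createElementNS(NS,'text');",
    "  t.setAttribute('x',n.x+0.12); t.setAttribute('y',n.y);",
    "  t.setAttribute('font-size',0.12); t.textContent=n.label;",
    "  g.appendChild(t);});",
    "var drag=null;",
    "svg.addEventListener('mousedown',function(e){drag=[e.clientX,e.clientY];});",
    "window.addEventListener('mouseup',function(){drag=null;});",
    "window.addEventListener('mousemove',function(e){",
    "  if(drag){tx+=e.clientX-drag[0]; ty+=e.clientY-drag[1]; drag=[e.clientX,e.clientY]; apply();}});",
    "svg.addEventListener('wheel',function(e){",
    "  e.preventDefault(); scale*=(e.deltaY<0?1.1:0.9); apply();},{passive:false});",
    "apply();",
    sep = "\n"
  )
}

#' Parse the embedded payload of a rendered HTML network back
#'
#' Extracts the JSON payload embedded by [render_html()] and reconstructs
#' the network document (nodes, edges, layout seed, palette), so exports
#' can be verified to round-trip.
#'
#' @param path An HTML file written by [render_html()].
#' @return An object of class `network_document`.
#' @export
read_html_document <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  html <- readChar(path, file.info(path)$size, useBytes = TRUE)
  open_at <- regexpr(html_payload_open, html, fixed = TRUE)
  if (open_at < 0) abort_input("no embedded network payload found in HTML")
  rest <- substring(html, open_at + nchar(html_payload_open))
  close_at <- regexpr(html_payload_close, rest, fixed = TRUE)
  payload <- substring(rest, 1, close_at - 1)
  parsed <- jsonlite::fromJSON(payload, simplifyVector = TRUE)
  empty_nodes <- tibble::tibble(
    id = character(), label = character(), kind = character(),
    shape = character(), color_key = character(),
    level = integer(), bin = character()
  )
  nodes <- if (length(parsed$nodes) == 0) empty_nodes else tibble::as_tibble(parsed$nodes)
  edges <- if (length(parsed$edges) == 0) {
    tibble::tibble(from = character(), to = character())
  } else {
    tibble::as_tibble(parsed$edges)
  }
  if (nrow(nodes) > 0) {
    nodes$level <- suppressWarnings(as.integer(nodes$level))
    nodes$bin <- as.character(nodes$bin)   # all-null columns parse as logical
  }
  new_network_document(
    nodes = nodes[intersect(names(empty_nodes), names(nodes))],
    edges = edges,
    layout_seed = parsed$layout_seed,
    palette = unlist(parsed$palette)
  )
}
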