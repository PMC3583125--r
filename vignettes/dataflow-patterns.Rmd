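---
title: "Dataflow patterns: the dagflow execution model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dataflow patterns: the dagflow execution model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagflow)
```

## The execution model

`dagflow` executes workflows under a dataflow discipline: a task fires
when and only when every in-port has received a token. The engine keeps a
per-node inbox; each round it collects the ready set, orders it
lexicographically by node id, dispatches up to `workers` slots, delivers
the produced tokens along edges, and repeats. On a single processor this
is equivalent to precomputing a *static schedule* — `wf_static_schedule()`
performs a Kahn traversal appending a node only after all its predecessors,
breaking ties lexicographically so the order is reproducible.

Two consequences of this design are worth stating explicitly:

* **Determinism in `workers`.** The executor contract is behavioral:
  `workers` bounds how many ready tasks are admitted per dispatch round,
  every admitted instance completes exactly once, and completion reports
  exit status and outputs. Instances are executed sequentially inside the
  dispatcher, so with deterministic tools the final outputs are
  byte-identical for any worker count — a property the test suite asserts
  for `workers ∈ {1, 2, 8}` rather than assumes.
* **Statelessness, no streaming.** Tasks communicate only through tokens;
  nothing flows between concurrently admitted tasks, and repeated runs on
  the same inputs give identical results.

Tokens have status `DATA` (payload text, possibly a recursively nested
list of tokens), `DUMMY` (satisfies readiness, never rendered into a
command) or `FAIL` (branch-pruning signal). A `FAIL` on any required
in-port skips the node — no process is spawned — and re-emits `FAIL` on
every out-port, so an entire subtree downstream of a rejected branch is
pruned. A `FAIL` and a runtime failure are deliberately distinct: a
nonzero tool exit is a run-level error that stops dispatch (fail-fast) and
identifies the failing instance, while `FAIL` tokens propagate silently.
Ports with the `control` role only ever carry `DUMMY`/`FAIL`; a `DATA`
token delivered to a control port is coerced to `DUMMY`, since such edges
encode pure execution dependencies.

Sub-workflows (composite nodes, iteration bodies, delegated components)
are executed by recursive self-invocation of the engine. Nesting depth is
capped at 32 with a clear error; the recursion otherwise has no guard and
runaway self-nesting would be indistinguishable from a hang.

## Patterns

**Multi-choice switch.** The predicate is evaluated once per firing; the
selected out-port passes the input token through, all others emit `FAIL`.
A boolean predicate is accepted for two-branch switches (`TRUE` selects
the first out-port); otherwise the predicate must name an out-port.

**Iteration** is a do-while: the body executes at least once; after each
pass the termination predicate sees the body outputs and the 1-based
iteration counter; on continuation the feedback map atomically overwrites
carried inputs with designated outputs. Exhausting `max_iterations`
without the predicate holding is a run error (`ITERATION_LIMIT`) by
default; setting the node parameter `on_limit = "warn"` demotes it to a
warning that accepts the final pass. Loop passes are stateless — state
lives only in the fed-back tokens.

**List expansion.** `MAP` produces one instance per item,
order-preserving. `DOT` pairs index-wise and *truncates to the shortest
list*, ignoring trailing items; with more than two lists the pairing is
index-wise up to the global minimum length. `CROSS` produces all tuples in
row-major order (first list outermost, last varying fastest). The
truncation and ordering conventions are fixed here because nothing forces
them; both are asserted against brute-force enumerators. Results are
reassembled into list tokens positionally, so output order equals input
order no matter when instances complete (the suite injects artificial
delays to check this). An instance whose bound item is itself `FAIL` is
pruned, not invoked.

**Select and collect.** `select` returns input `a` if Ψ holds, else `b`.
Two extensions make switch→branches→join wiring work without user
boilerplate: if exactly one input is `FAIL` the other is returned without
evaluating Ψ, and if both are `FAIL` the output is `FAIL`. `collect`
concatenates its inputs in declared port order into a list token, keeping
list inputs nested; `FAIL` items are dropped (all-`FAIL` yields `FAIL`),
and `DUMMY` items — which carry nothing collectable — are dropped too.

**`split_into_list`** parses a multi-FASTA payload (via Biostrings) and
yields either one item per record or ⌈N/k⌉ blocks of at most `k` records;
records are never split across blocks and order is preserved. The `k = 10`
default in the bundled fixture is a desk-scale choice; the semantics are
exactly ⌈N/k⌉. When a list token later reaches a scalar port it is
serialized to a single stream with the block separator (default `%%%`) on
its own line.

## Predicates

Ψ functions and termination criteria are user-defined, so two predicate
kinds are supported:

* **expression** — a small safe language: the expression is parsed and
  evaluated in an environment exposing only the bound variables
  (`payload`, `value`, `a`, `b`, `iteration`, `input(port)`) and a
  whitelist of pure base functions (`grepl`, `nchar`, `substr`,
  comparisons, arithmetic, ...). There is deliberately no general code
  execution: the environment's parent is empty, so `system`, file access
  and friends are simply absent.
* **program** — a path to any executable honoring a fixed CLI contract: it
  receives the bound inputs staged as files (one argument per port, port
  order), prints the chosen out-port name or `true`/`false`, and exits 0.
  This keeps user termination criteria language-neutral.

Evaluation is deterministic for fixed inputs in both kinds.

## Parameters

Node parameters are attributes of the node (not input items), with a total
precedence order resolved per parameter at invocation time:

`runtime parameter file > edge-delivered parameter token > node attribute > tool default`

A runtime file (`wf_apply_params()`) may only name parameters declared by
the node or its tool; unknown names are rejected with the declared list.
Ports with the `parameter` role turn an incoming `DATA` payload into a
parameter value of the port's name.

## The native format and the foreign dialects

The native carrier is JSON with explicit pattern kinds and
parameters-as-attributes. `wf_save()` is canonical — nodes sorted by id,
edges by destination, fixed key order — so equal graphs serialize to equal
bytes and `wf_load()` round-trips; acyclicity and all structural
invariants are re-checked on every load and after every transformation.

Two foreign dialects are *documented simplified subsets*, re-designed from
the behavior of real systems rather than byte-compatible with them:

* **JSON step dialect** — `{"steps": {"<id>": {"name", "type"
  ("tool" | "data_input"), "tool_id", "tool_state", "input_connections":
  {"<in_port>": {"id", "output_name"}}}}}`. One node per step, one edge per
  connection, `tool_state` → node attributes; unwired ports are exposed.
* **XML processor dialect** — a `<workflow>` root holding `<source>`,
  `<sink from="node:port">`, `<processor type="local|remote|workflow">`,
  `<link from="a:out" to="b:in"/>` and
  `<conditional test="..."><case port="p" to="node:port"/></conditional>`
  elements. The rewrite rules: local processors → tool nodes; conditionals
  → switch nodes whose non-selected branches are pruned by `FAIL` wiring;
  nested workflows → composite nodes; remote processors → external nodes
  carrying a `(operation, endpoint)` service signature.

A service catalog maps signatures to local tools: operations match
case-sensitively, endpoint hosts against a case-insensitive glob. A
matched external node becomes a local tool node with ports remapped
through the entry's port map, which must be a bijection onto the local
tool's declared ports; everything else in the graph is untouched.
Unmatched services stay external.

## The optimizer and the delegation contract

External nodes are executed by a foreign engine through a command-line
contract: the sub-workflow and its inputs are staged to a directory
(`body.json`, `inputs/<port>`), the engine command (placeholders `{body}`,
`{inputs}`, `{outputs}`) is invoked once, and declared outputs are
collected from `outputs/<port>`. The package ships a stub engine
(`inst/exec/stub_engine.R`) that honors the contract by running the body
with the native engine in a subprocess; with `engine_cmd = NULL`
delegation runs in-process. Either way each delegation is one trace event.

Invoking the engine once per external node is wasteful, so
`wf_find_external_subworkflows()` grows *maximal external sub-workflows*
greedily: seeds are taken in lexicographic order; adjacent external nodes
are added whenever condensing the tentative component (alongside the
already-fixed ones) keeps the graph acyclic; rejected candidates are
retried after the component grows, until a fixpoint. Encapsulation
replaces each component with one composite external node whose body is the
induced sub-graph (inner externals become plain tool nodes — the foreign
engine runs them natively), re-wiring boundary edges 1:1 to fresh ports.

Two design points were genuinely open:

* **Retry behavior.** A candidate rejected early may become admissible
  after the component grows, hence the fixpoint loop rather than a single
  greedy sweep.
* **Maximality and uniqueness.** The partition is generally not unique:
  distinct maximal partitions can coexist in which a single node could be
  carried laterally from one component to the other, in either direction,
  without creating a cycle. A "no node can move to an adjacent component"
  criterion is therefore unsatisfiable on some graphs. The package's
  testable definition is order-independent *merge maximality* — no two
  components of the returned partition can be merged into one weakly
  connected, condensable-without-cycle component — plus the deterministic
  lexicographic seed order as the tie-break among coexisting maximal
  partitions. The suite verifies the returned partition against an
  exhaustive search over all set partitions of the external nodes under
  this definition, and verifies that encapsulated execution is
  byte-identical to the original with exactly one delegation per
  component.

## Stub tools and synthetic data

All bundled tools are pure, byte-deterministic functions of their input
payloads: `identity`, `revseq`, `upper`, `translate1` (frame-1 standard
codon table), `lenfilter(min_len)`, `toyblast` (distinct shared k-mers,
`k = 3`, of each query record against each database record), `covfilter`
(`min_score` on each query's *best* score; all hit rows of surviving
queries are kept), `consensus` (per-column majority, alphabetical
tie-break, equal-length inputs required), `taxcount` (tally of database
labels — the id prefix before the first underscore), plus plumbing stubs
`concat`, `idexclude` and `retrieve`. They stand in for real search and
alignment programs so that everything runs offline in seconds; a real tool
is registered with the same `wf_tool()` mechanism and a command template,
rendered to an argv vector (never a shell string) in a per-instance
scratch directory.

The synthetic generators emulate *structure*, not biology: uniform random
sequences have no phylogenetic signal, toy k-mer scores at `k = 3` are
weakly discriminative, and the toy databases are tiny generated FASTA
files checked in as versioned fixtures. Passing tests therefore
demonstrate the orchestration semantics — expansion counts, routing,
ordering, determinism, equivalence under encapsulation — and say nothing
about the biological quality of results obtained with real tools.

Problem sizes used throughout are the package's own desk-scale choices:
the metagenomics fixture uses 110 toy reads split into ⌈110/10⌉ = 11
blocks crossed with 3 databases (33 search instances); pattern
cardinalities are checked on 1000 random list-length cases (lengths ≤ 6);
schedules on exhaustively enumerated topological-order sets for DAGs of up
to 6 nodes plus 500 random executions; the optimizer against exhaustive
partition search for labeled DAGs of up to 7 nodes and 100 random
encapsulation equivalences.

## Degenerate inputs and numerical conventions

* Empty list on an expansion port: zero instances, empty list output.
* Empty FASTA into the splitter: an empty list; unparseable FASTA is a
  format error carrying the offending line number.
* Both `select` inputs `FAIL` / all `collect` inputs `FAIL`: `FAIL` out.
* `DOT` with unequal lengths truncates (documented above); erroring was
  considered and rejected because truncation composes better with
  upstream filters that may shorten one list.
* Identifiers and port names are case-sensitive; ports are referenced by
  name, never by index; one edge per destination in-port makes token
  arrival unambiguous (fan-in goes through `collect`/`select`).
* In the protein-analysis fixture the two switch branches are joined by a
  `select` node rather than a `collect`: the one-sided `FAIL` bypass
  returns the surviving branch directly, whereas collecting would wrap it
  in a one-element list that the downstream search stub would have to
  unwrap.

## Limitations

* No streaming, checkpoint/restart, or cluster/cloud backends; the
  executor abstraction stops at slot-bounded dispatch with exactly-once
  completion.
* The dispatcher runs instances sequentially; `workers` shapes dispatch
  order and models slots but does not use OS-level parallelism.
* The foreign dialect parsers cover the documented subsets only; real
  SCUFL/t2flow or Galaxy exports need conversion into those subsets.
* Payloads move inline as text staged to files per instance; very large
  intermediates would want file-reference payloads throughout.
* A failed list job fails the run after the current dispatch round;
  already-admitted sibling instances finish, no new ones start, and there
  is no cancellation of in-flight work.
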