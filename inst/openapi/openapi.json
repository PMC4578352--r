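{
  "openapi": "3.0.3",
  "info": {
    "title": "enmkit service layer",
    "version": "1.0.0",
    "description": "Substance, study, bundle and query resources over an in-memory nanomaterial store. All list routes paginate with ?page=&pagesize=."
  },
  "paths": {
    "/substance": {
      "get": {
        "summary": "List / search substances",
        "parameters": [
          {"name": "page", "in": "query", "schema": {"type": "integer", "default": 0}},
          {"name": "pagesize", "in": "query", "schema": {"type": "integer", "default": 10}}
        ],
        "responses": {"200": {"description": "paginated substance list"}}
      },
      "post": {
        "summary": "Upload a template workbook",
        "requestBody": {
          "content": {"application/json": {"schema": {
            "type": "object",
            "properties": {
              "file": {"type": "string", "description": "workbook path"},
              "template": {"type": "string", "description": "mapping configuration path"},
              "clearComposition": {"type": "boolean"},
              "clearStudies": {"type": "boolean"}
            }}}}
        },
        "responses": {"200": {"description": "import summary"},
                       "400": {"description": "malformed upload with diagnostics"}}
      }
    },
    "/substance/{uuid}": {"get": {"summary": "One substance", "responses": {"200": {"description": "substance"}, "404": {"description": "unknown uuid"}}}},
    "/substance/{uuid}/composition": {"get": {"summary": "Components of a substance", "responses": {"200": {"description": "component list"}}}},
    "/substance/{uuid}/study": {"get": {"summary": "Study JSON documents of a substance", "responses": {"200": {"description": "study array"}}}},
    "/substance/{uuid}/studysummary": {"get": {"summary": "Endpoint summary restricted to one substance", "responses": {"200": {"description": "summary rows"}}}},
    "/bundle": {
      "get": {"summary": "List bundles", "responses": {"200": {"description": "paginated bundle list"}}},
      "post": {"summary": "Create a bundle", "responses": {"200": {"description": "bundle id"}}}
    },
    "/bundle/{id}": {"get": {"summary": "One bundle", "responses": {"200": {"description": "bundle"}}}},
    "/bundle/{id}/substance": {"put": {"summary": "Select or deselect a substance (body: {uuid, action})", "responses": {"200": {"description": "updated membership"}}}},
    "/bundle/{id}/property": {"put": {"summary": "Select or deselect an endpoint (body: {topcategory, category, endpoint, conditions, action})", "responses": {"200": {"description": "updated selections"}}}},
    "/bundle/{id}/matrix": {"get": {"summary": "Aggregated modelling matrix of the bundle", "responses": {"200": {"description": "matrix with per-cell aggregation reports"}}}},
    "/query": {
      "get": {
        "summary": "Similarity search (smiles, threshold) or endpoint summary filter (topcategory, category, endpoint)",
        "parameters": [
          {"name": "smiles", "in": "query", "schema": {"type": "string"}},
          {"name": "threshold", "in": "query", "schema": {"type": "number", "default": 0.6}},
          {"name": "topcategory", "in": "query", "schema": {"type": "string"}},
          {"name": "category", "in": "query", "schema": {"type": "string"}},
          {"name": "endpoint", "in": "query", "schema": {"type": "string"}}
        ],
        "responses": {"200": {"description": "hits"}}
      }
    }
  }
}
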