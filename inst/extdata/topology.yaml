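# Reference consortium: three organizations in one channel, two
# endorser-validator-committer (EVC) nodes and three storage nodes each,
# one orderer, one consortium.
consortium_id: elm-consortium
channels:
  - channel_id: main
    organizations: [uni-london, hospital-oslo, cloud-bergen]
organizations:
  - org_id: uni-london
    domain_name: london.example.ac.uk
    evc_nodes: 2
    storage_nodes: 3
  - org_id: hospital-oslo
    domain_name: oslo.example.no
    evc_nodes: 2
    storage_nodes: 3
  - org_id: cloud-bergen
    domain_name: bergen.example.no
    evc_nodes: 2
    storage_nodes: 3
users:
  - user_id: alice
    org_id: uni-london
    secret: alice-secret
    admin: true
  - user_id: bob
    org_id: hospital-oslo
    secret: bob-secret
    admin: false
  - user_id: carol
    org_id: cloud-bergen
    secret: carol-secret
    admin: false
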