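# synthetic protein-protein interaction network (generated, not a real interactome)
# 120 nodes, disassortative wiring planted at r ~ -0.3
SYNP019	SYNP105
SYNP016	SYNP108
SYNP105	SYNP116
SYNP063	SYNP097
SYNP069	SYNP101
SYNP027	SYNP113
SYNP027	SYNP048
SYNP095	SYNP101
SYNP053	SYNP114
SYNP006	SYNP103
SYNP067	SYNP082
SYNP047	SYNP078
SYNP028	SYNP119
SYNP055	SYNP113
SYNP109	SYNP111
SYNP011	SYNP033
SYNP080	SYNP104
SYNP060	SYNP114
SYNP030	SYNP095
SYNP018	SYNP104
SYNP002	SYNP118
SYNP052	SYNP114
SYNP001	SYNP115
SYNP094	SYNP120
SYNP032	SYNP096
SYNP065	SYNP101
SYNP050	SYNP110
SYNP003	SYNP058
SYNP079	SYNP085
SYNP106	SYNP116
SYNP001	SYNP004
SYNP020	SYNP064
SYNP031	SYNP062
SYNP024	SYNP033
SYNP002	SYNP030
SYNP079	SYNP091
SYNP018	SYNP056
SYNP005	SYNP120
SYNP098	SYNP104
SYNP071	SYNP096
SYNP027	SYNP068
SYNP114	SYNP119
SYNP050	SYNP098
SYNP014	SYNP109
SYNP006	SYNP085
SYNP028	SYNP082
SYNP052	SYNP061
SYNP008	SYNP054
SYNP046	SYNP082
SYNP041	SYNP085
SYNP028	SYNP044
SYNP070	SYNP097
SYNP004	SYNP030
SYNP068	SYNP114
SYNP075	SYNP084
SYNP046	SYNP047
SYNP006	SYNP061
SYNP065	SYNP087
SYNP088	SYNP097
SYNP085	SYNP096
SYNP012	SYNP033
SYNP052	SYNP108
SYNP102	SYNP116
SYNP047	SYNP107
SYNP037	SYNP043
SYNP074	SYNP107
SYNP070	SYNP106
SYNP028	SYNP080
SYNP069	SYNP108
SYNP059	SYNP110
SYNP041	SYNP104
SYNP014	SYNP070
SYNP095	SYNP098
SYNP035	SYNP079
SYNP063	SYNP093
SYNP006	SYNP079
SYNP054	SYNP080
SYNP102	SYNP103
SYNP016	SYNP040
SYNP038	SYNP054
SYNP020	SYNP110
SYNP020	SYNP027
SYNP009	SYNP020
SYNP027	SYNP105
SYNP038	SYNP050
SYNP031	SYNP114
SYNP048	SYNP082
SYNP019	SYNP095
SYNP079	SYNP084
SYNP014	SYNP073
SYNP045	SYNP084
SYNP036	SYNP074
SYNP091	SYNP102
SYNP067	SYNP081
SYNP025	SYNP078
SYNP039	SYNP093
SYNP087	SYNP104
SYNP037	SYNP076
SYNP033	SYNP113
SYNP086	SYNP094
SYNP046	SYNP113
SYNP011	SYNP070
SYNP021	SYNP039
SYNP030	SYNP048
SYNP005	SYNP032
SYNP049	SYNP104
SYNP037	SYNP107
SYNP038	SYNP043
SYNP051	SYNP065
SYNP038	SYNP109
SYNP074	SYNP085
SYNP035	SYNP082
SYNP048	SYNP077
SYNP054	SYNP075
SYNP022	SYNP084
SYNP112	SYNP120
SYNP044	SYNP104
SYNP065	SYNP107
SYNP054	SYNP068
SYNP081	SYNP107
SYNP054	SYNP077
SYNP002	SYNP078
SYNP092	SYNP098
SYNP019	SYNP075
SYNP104	SYNP111
SYNP045	SYNP072
SYNP063	SYNP072
SYNP023	SYNP056
SYNP094	SYNP099
SYNP084	SYNP102
SYNP016	SYNP075
SYNP011	SYNP038
SYNP038	SYNP049
SYNP010	SYNP012
SYNP056	SYNP086
SYNP102	SYNP120
SYNP023	SYNP036
SYNP001	SYNP088
SYNP015	SYNP111
SYNP094	SYNP098
SYNP017	SYNP026
SYNP058	SYNP094
SYNP039	SYNP084
SYNP110	SYNP113
SYNP011	SYNP036
SYNP027	SYNP112
SYNP003	SYNP111
SYNP094	SYNP095
SYNP053	SYNP097
SYNP005	SYNP044
SYNP041	SYNP086
SYNP025	SYNP104
SYNP108	SYNP113
SYNP107	SYNP117
SYNP074	SYNP102
SYNP028	SYNP076
SYNP003	SYNP107
SYNP105	SYNP119
SYNP088	SYNP093
SYNP005	SYNP058
SYNP088	SYNP091
SYNP039	SYNP065
SYNP023	SYNP027
SYNP102	SYNP113
SYNP028	SYNP096
SYNP100	SYNP116
SYNP016	SYNP096
SYNP039	SYNP067
SYNP007	SYNP087
SYNP090	SYNP096
SYNP106	SYNP115
SYNP044	SYNP050
SYNP034	SYNP035
SYNP006	SYNP063
SYNP073	SYNP115
SYNP002	SYNP091
SYNP025	SYNP101
SYNP005	SYNP054
SYNP001	SYNP030
SYNP005	SYNP031
SYNP009	SYNP083
SYNP028	SYNP086
SYNP038	SYNP052
SYNP010	SYNP028
SYNP005	SYNP014
SYNP076	SYNP114
SYNP108	SYNP116
SYNP043	SYNP067
SYNP048	SYNP059
SYNP049	SYNP102
SYNP058	SYNP059
SYNP028	SYNP035
SYNP017	SYNP109
SYNP043	SYNP095
SYNP062	SYNP094
SYNP045	SYNP065
SYNP006	SYNP032
SYNP037	SYNP075
SYNP082	SYNP106
SYNP012	SYNP020
SYNP020	SYNP089
SYNP012	SYNP097
SYNP084	SYNP093
SYNP001	SYNP047
SYNP021	SYNP036
SYNP072	SYNP092
SYNP010	SYNP110
SYNP021	SYNP075
SYNP015	SYNP093
SYNP034	SYNP047
SYNP063	SYNP104
SYNP109	SYNP119
SYNP021	SYNP065
SYNP009	SYNP097
SYNP046	SYNP077
SYNP042	SYNP045
SYNP101	SYNP106
SYNP063	SYNP066
SYNP089	SYNP110
SYNP006	SYNP092
SYNP017	SYNP114
SYNP045	SYNP054
SYNP094	SYNP103
SYNP041	SYNP101
SYNP033	SYNP116
SYNP028	SYNP099
SYNP023	SYNP067
SYNP002	SYNP050
SYNP056	SYNP082
SYNP061	SYNP110
SYNP001	SYNP053
SYNP004	SYNP040
SYNP033	SYNP063
SYNP103	SYNP114
SYNP006	SYNP099
SYNP006	SYNP014
SYNP068	SYNP075
SYNP012	SYNP029
SYNP040	SYNP067
SYNP004	SYNP005
SYNP077	SYNP093
SYNP011	SYNP117
SYNP032	SYNP078
SYNP055	SYNP119
SYNP013
SYNP057
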