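sample_id	taxon_label	n_count	approximate	structure	locality_id	reference	multivalents_observed
KL-49-97	P. emmeli	79	FALSE	1L+1M	Gnishik	This study	FALSE
183A07	P. emmeli	ca79	TRUE	1L+1M	Sevan_Lake	This study	FALSE
146A08	P. emmeli	ca78	TRUE	1L+1M	Gnishik	This study	FALSE
150A08	P. emmeli	78	FALSE	1L+1M	Gnishik	This study	FALSE
152A08	P. emmeli	78	FALSE	1L+1M	Gnishik	This study	FALSE
157A08	P. emmeli	78	FALSE	1L+1M	Gnishik	This study	FALSE
158A08	P. emmeli	79	FALSE	1L+1M	Gnishik	This study	FALSE
318A08	P. emmeli	78	FALSE	1L+1M	Gnishik	This study	FALSE
319A08	P. emmeli	ca78	TRUE	1L+1M	Gnishik	This study	FALSE
320A08	P. emmeli	77	FALSE	1L+1M	Gnishik	This study	FALSE
321A08	P. emmeli	ca77	TRUE	1L+1M	Gnishik	This study	FALSE
234K16A	P. emmeli	77	FALSE	1L+1M	Vayots_Dzor	This study	FALSE
243K16A	P. emmeli	77	FALSE	1L+1M	Sevan_Lake_Madina	This study	FALSE
584K15	P. emmeli	77	FALSE	1L+1M	Sevan_Lake_Artanish	This study	FALSE
022K19	P. ripartii ripartii	90	FALSE	1L+1M	Jirgatol	This study	FALSE
Dan2001-13	P. ripartii paralcestis	ca90	TRUE	1L+1M	Ja_Joor_pass	This study	FALSE
198A08	P. ripartii kalashiani	ca90	TRUE	1L+1M	Shvanidzor	This study	FALSE
201A08	P. ripartii kalashiani	ca90	TRUE	1L+1M	Shvanidzor	This study	FALSE
209A08	P. ripartii kalashiani	ca90	TRUE	1L+1M	Shvanidzor	This study	FALSE
E250	P. keleybaricus	ca86	TRUE	1L+1M	Keleybar_Makidi	This study	FALSE
E258	P. keleybaricus	ca86	TRUE	1L+1M	Keleybar_Makidi	This study	FALSE
E260	P. keleybaricus	86	FALSE	1L+1M	Keleybar_Makidi	This study	FALSE
E261	P. keleybaricus	ca86	TRUE	1L+1M	Keleybar_Makidi	This study	FALSE
E262	P. keleybaricus	86	FALSE	1L+1M	Keleybar_Makidi	This study	FALSE
E311	P. admetus	79	FALSE	1L+0M	Varzagan	This study	FALSE
KL-34-96	P. admetus yeranyani	ca80	TRUE	1L+0M	Aragats	This study	FALSE
KL-50-97	P. admetus yeranyani	79	FALSE	1L+0M	Aragats	This study	FALSE
KL-67-97	P. admetus yeranyani	79	FALSE	1L+0M	Megri_Lichk	This study	FALSE
154A08	P. admetus yeranyani	79	FALSE	1L+0M	Gnishik	This study	FALSE
211A08	P. admetus yeranyani	79	FALSE	1L+0M	Gyumarants	This study	FALSE
KL-28-97	P. demavendi belovi	74	FALSE	2L+2M	Khosrov	This study	FALSE
003A07	P. demavendi belovi	73	FALSE	2L+2M	Gnishik	This study	FALSE
050A07	P. demavendi belovi	74	FALSE	2L+2M	Khosrov	This study	FALSE
051A07	P. demavendi belovi	74	FALSE	2L+2M	Khosrov	This study	FALSE
054A07	P. demavendi belovi	74	FALSE	2L+2M	Khosrov	This study	FALSE
064A07	P. demavendi belovi	73	FALSE	2L+2M	Khosrov	This study	FALSE
070A07	P. demavendi belovi	73	FALSE	2L+2M	Khosrov	This study	FALSE
077A08	P. demavendi belovi	74	FALSE	2L+2M	Gnishik	This study	FALSE
079A08	P. demavendi belovi	74	FALSE	2L+2M	Gnishik	This study	FALSE
106A08	P. demavendi belovi	73	FALSE	2L+2M	Khosrov	This study	FALSE
121A07	P. demavendi belovi	75	FALSE	2L+2M	Vohkchaberd	This study	FALSE
2002Q479	P. demavendi belovi	ca73	TRUE	2L+2M	Khosrov	This study	FALSE
138A07	P. demavendi antonius	ca72	TRUE	2L+2M	Sevan_Lake	This study	FALSE
140A07	P. demavendi antonius	71	FALSE	2L+2M	Sevan_Lake	This study	FALSE
151A07	P. demavendi antonius	71	FALSE	2L+2M	Sevan_Lake	This study	FALSE
184A07	P. demavendi antonius	ca73	TRUE	2L+2M	Sevan_Lake	This study	FALSE
192A07	P. demavendi antonius	71	FALSE	2L+2M	Sevan_Lake	This study	FALSE
195A07	P. demavendi antonius	ca71	TRUE	2L+2M	Sevan_Lake	This study	FALSE
KL-1996-34-1	P. eriwanensis	ca32	TRUE	0L+0M	Aragats	Prior study	FALSE
KL-1997-6-1	P. eriwanensis	ca34	TRUE	0L+0M	Garny	Prior study	FALSE
KL-1997-6-4	P. eriwanensis	ca31	TRUE	0L+0M	Garny	Prior study	FALSE
KL-1997-6-7	P. eriwanensis	34	FALSE	0L+0M	Garny	Prior study	FALSE
KL-1997-6-8	P. eriwanensis	ca34	TRUE	0L+0M	Garny	Prior study	FALSE
KL-1997-6-9	P. eriwanensis	33	FALSE	0L+0M	Garny	Prior study	FALSE
KL-1997-7	P. eriwanensis	29	FALSE	0L+0M	Garny	Prior study	FALSE
KL-1997-76-1	P. eriwanensis	34	FALSE	0L+0M	Gnishik	Prior study	FALSE
AD2001-Nr4	P. eriwanensis	ca30	TRUE	0L+0M	Geghadir	Prior study	FALSE
AD2001-008	P. eriwanensis	34	FALSE	0L+0M	Gnishik	Prior study	FALSE
001A07	P. eriwanensis	34	FALSE	0L+0M	Gnishik	Prior study	FALSE
002A07	P. eriwanensis	32	FALSE	0L+0M	Gnishik	Prior study	FALSE
004A07	P. eriwanensis	32	FALSE	0L+0M	Gnishik	Prior study	FALSE
004A09	P. eriwanensis	ca32	TRUE	0L+0M	Gnishik	Prior study	FALSE
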